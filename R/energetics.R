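#' Point-charge set
#'
#' @param q charges in units of e.
#' @param xyz n x 3 matrix of coordinates, Angstrom.
#' @param radius optional per-atom radii, Angstrom.
#' @param source provenance tag ("synthetic" or a file path).
#' @return object of class `pnpb_charges`.
#' @export
point_charges <- function(q, xyz, radius = NULL, source = "synthetic") {
  xyz <- as.matrix(xyz)
  if (length(q) == 0) {
    xyz <- matrix(numeric(0), 0, 3)
  }
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(q),
            all(is.finite(q)), all(is.finite(xyz)))
  if (!is.null(radius)) stopifnot(length(radius) == length(q))
  structure(list(q = as.numeric(q), xyz = xyz, radius = radius,
                 source = source),
            class = "pnpb_charges")
}

#' @export
print.pnpb_charges <- function(x, ...) {
  cat(sprintf("Point-charge set: %d atoms, total charge %.4f e (%s)\n",
              length(x$q), sum(x$q), x$source))
  invisible(x)
}

#' Ion binding site
#'
#' A spherical site of radius `a_site` (the occupying ion's radius) at
#' `center`, probed at six symmetric surface points (the axis-aligned
#' points of the sphere), inside a cavity of volume `V_site` and dielectric
#' constant `eps_b`.
#'
#' @param center length-3 site center, Angstrom.
#' @param a_site radius of the occupying ion, Angstrom.
#' @param z_site valence of the occupying ion.
#' @param V_site volume available to the ion at the site, A^3; must exceed
#'   the ion volume.
#' @param eps_b cavity dielectric constant.
#' @param occupied logical, whether an ion currently occupies the site.
#' @param axes 3 x 3 rotation matrix giving the local frame of the six
#'   probe points (columns are the probe axes); identity by default.
#' @return object of class `pnpb_site`.
#' @export
binding_site <- function(center, a_site, z_site, V_site, eps_b = 3.6,
                         occupied = TRUE, axes = diag(3)) {
  stopifnot(length(center) == 3, a_site > 0, V_site > sphere_volume(a_site))
  probes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)) * a_site
  probes <- probes %*% t(axes)
  probes <- sweep(probes, 2, center, "+")
  structure(list(center = as.numeric(center), a_site = a_site,
                 z_site = z_site, V_site = V_site, eps_b = eps_b,
                 probes = probes, occupied = occupied),
            class = "pnpb_site")
}

#' Distance-dependent dielectric profile
#'
#' Sigmoidal screening function `eps_p(r) = 1 + 77 r / (27.7 + r)` used for
#' protein interiors: vacuum response at contact, bulk-water response
#' (eps = 78) far away.
#'
#' @param r distance(s), Angstrom, >= 0.
#' @return dielectric constant(s).
#' @export
dielectric_profile <- function(r) {
  if (any(r < 0)) stop("distance must be >= 0")
  1 + 77 * r / (27.7 + r)
}

#' Electric potential at a binding site from a point-charge structure
#'
#' Six-probe average of the screened Coulomb potential of all structure
#' charges plus the Born self-term of the occupying ion:
#' `phi = (1/4 pi eps0) [ (1/6) sum_k sum_j q_j / (eps_p(r_j) |c_j - A_k|)
#'   + q_site / (eps_b a_site) ]`,
#' with `r_j = |c_j - c_site|` the atom-to-site-center distance setting the
#' local dielectric. Reported in kBT/e.
#'
#' @param charges a `pnpb_charges` (may be empty: Born term only).
#' @param site a `pnpb_site`.
#' @param T temperature, K (sets the kBT/e conversion).
#' @param eps_p dielectric profile function of distance; defaults to
#'   [dielectric_profile()].
#' @param include_born logical, include the ion's own Born term.
#' @return potential in kBT/e.
#' @export
site_electric_potential <- function(charges, site, T = 298.15,
                                    eps_p = dielectric_profile,
                                    include_born = TRUE) {
  lB_vac <- bjerrum_length(1, T)   # e^2/(4 pi eps0 kBT) in Angstrom
  tot <- 0
  if (length(charges$q) > 0) {
    rj <- sqrt(rowSums(sweep(charges$xyz, 2, site$center, "-")^2))
    epj <- eps_p(rj)
    d <- sqrt(outer(rowSums(charges$xyz^2), rowSums(site$probes^2), "+") -
                2 * charges$xyz %*% t(site$probes))
    if (any(d < 1e-9))
      stop("coincident charge and probe point: zero distance in the ",
           "six-probe sum", call. = FALSE)
    tot <- mean(colSums(charges$q / (epj * d)))
  }
  if (include_born)
    tot <- tot + site$z_site / (site$eps_b * site$a_site)
  lB_vac * tot
}

#' Steric potential of an ion at a binding site
#'
#' `S = ln[(1 - v_site/V_site) / Gamma_B]`: the local void fraction left by
#' the ion in its site volume, relative to the bulk void fraction of the
#' bath composition.
#'
#' @param site a `pnpb_site` (uses `a_site` for the ion volume and
#'   `V_site`).
#' @param comp the bath `pnpb_composition` (provides `Gamma_B`).
#' @param weight either "none" (report S itself, the default) or "v_v0"
#'   (report `(v_site/v0) S` with `v0` the bath average particle volume).
#' @return dimensionless steric potential (kBT when multiplied by -v/v0 in
#'   the energy bookkeeping).
#' @export
site_steric_potential <- function(site, comp, weight = c("none", "v_v0")) {
  weight <- match.arg(weight)
  v_ion <- sphere_volume(site$a_site)
  if (site$V_site <= v_ion)
    stop("over-packed site: V_site <= ion volume", call. = FALSE)
  S <- log((1 - v_ion / site$V_site) / comp$Gamma_B)
  if (weight == "v_v0") S <- (v_ion / comp$v0) * S
  S
}

#' Relative free energies of two ions between pore and bulk
#'
#' `dG(ion) = G_pore - G_bulk` for each ion and the selectivity difference
#' `ddG = dG(ion2) - dG(ion1)`; positive `ddG` means ion2 is disfavoured
#' in the pore relative to ion1.
#'
#' @param G_pore,G_bulk named numeric vectors (same two names), kcal/mol.
#' @return list with `dG` (named) and `ddG` (`dG[2] - dG[1]`).
#' @export
free_energy_balance <- function(G_pore, G_bulk) {
  stopifnot(length(G_pore) == 2, length(G_bulk) == 2,
            !is.null(names(G_pore)), all(names(G_pore) == names(G_bulk)))
  dG <- G_pore - G_bulk
  list(dG = dG, ddG = unname(dG[2] - dG[1]))
}

#' Total (electric + steric) potential states of occupied sites
#'
#' For each occupied site, the total potential is the six-probe electric
#' potential generated by the structure charges and by the ions occupying
#' the other sites, plus the site steric term. Sites with negative total
#' potential are classified stable.
#'
#' @param charges a `pnpb_charges` for the fixed structure (may be empty).
#' @param sites list of `pnpb_site` objects (with `occupied` flags).
#' @param comp bath `pnpb_composition`.
#' @param T temperature, K.
#' @param steric_weight passed to [site_steric_potential()].
#' @return data.frame with per-site `electric` (kBT/e), `steric`, `total`
#'   and `stable`.
#' @export
total_potential_state <- function(charges, sites, comp, T = 298.15,
                                  steric_weight = "none") {
  occ <- vapply(sites, function(s) isTRUE(s$occupied), logical(1))
  centers <- t(vapply(sites, function(s) s$center, numeric(3)))
  if (sum(occ) > 1) {
    dd <- as.matrix(stats::dist(centers[occ, , drop = FALSE]))
    rads <- vapply(sites[occ], function(s) s$a_site, numeric(1))
    if (any(dd[upper.tri(dd)] < (outer(rads, rads, "+"))[upper.tri(dd)]))
      stop("geometry error: occupied sites overlap", call. = FALSE)
  }
  out <- lapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    if (!occ[i]) return(NULL)
    others <- which(occ & seq_along(sites) != i)
    qs <- charges$q
    xs <- charges$xyz
    if (length(others)) {
      qs <- c(qs, vapply(sites[others], function(o) o$z_site, numeric(1)))
      xs <- rbind(xs, centers[others, , drop = FALSE])
    }
    ext <- point_charges(qs, xs, source = "assembled")
    el <- site_electric_potential(ext, s, T)
    st <- site_steric_potential(s, comp, steric_weight)
    data.frame(site = i, electric = el, steric = st,
               total = el + st, stable = (el + st) < 0)
  })
  do.call(rbind, out)
}
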