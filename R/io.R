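#' Read a scenario configuration file
#'
#' YAML configuration with blocks `composition` (list of species with
#' `name`, `z`, `radius_A`, `conc_M`, plus `temperature_K`), and optional
#' `domain`, `solver`, `transport` and `site` blocks mirroring the
#' arguments of [domain_spec()], [solver_config()], [transport_spec()] and
#' [binding_site()]. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return list with parsed `composition` (a `pnpb_composition`) and the
#'   raw validated blocks.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("composition", "temperature_K", "domain", "solver",
             "transport", "site")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$composition))
    stop("configuration must contain a `composition` block")
  sp <- do.call(rbind, lapply(cfg$composition, function(s) {
    need <- c("name", "z", "radius_A", "conc_M")
    extra <- setdiff(names(s), need)
    if (length(extra))
      stop("unknown species keys: ", paste(extra, collapse = ", "),
           call. = FALSE)
    data.frame(name = s$name, z = s$z, radius_A = s$radius_A,
               conc_M = s$conc_M)
  }))
  T <- if (is.null(cfg$temperature_K)) 298.15 else cfg$temperature_K
  comp <- make_composition(sp, T = T)
  domain <- if (!is.null(cfg$domain)) do.call(domain_spec, cfg$domain)
  solver <- if (!is.null(cfg$solver)) do.call(solver_config, cfg$solver)
    else solver_config()
  list(composition = comp, domain = domain, solver = solver,
       transport = cfg$transport, site = cfg$site, raw = cfg)
}

#' Write a field state as a tab-separated profile
#'
#' Columns: `x`, `phi`, `Psi` (when present), one column per species
#' concentration (molar), `Gamma`, `S`.
#'
#' @param state a `pnpb_field_state` (or the `state` element of a
#'   transport solve).
#' @param path output TSV path.
#' @return invisibly, the written data.frame.
#' @export
write_profile_tsv <- function(state, path) {
  df <- data.frame(x = state$x, phi = state$phi)
  if (!is.null(state$Psi)) df$Psi <- state$Psi
  Cm <- number_to_molar(state$C)
  colnames(Cm) <- paste0("C_", colnames(Cm), "_M")
  df <- cbind(df, Cm, Gamma = state$Gamma, S = state$S)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

#' Generate deterministic synthetic fixtures
#'
#' Known-answer inputs for tests and demonstrations:
#' \describe{
#'   \item{edl_1to4}{the planar double-layer scenario config of a 0.1 M
#'     1:4 electrolyte at a wall charged with 1e/50 A^2 (ion radius 4.65 A,
#'     water 1.4 A at 55.5 M, correlation length 1.6 x 4.65 A, eps 80).}
#'   \item{salt_table}{an activity-coefficient table synthesized from given
#'     Born-scaling parameters.}
#'   \item{random_charges}{a reproducible random point-charge cloud.}
#'   \item{toy_pocket}{a four-site binding pocket with unit charges.}
#' }
#' Identical seeds give identical outputs.
#'
#' @param name generator name.
#' @param seed integer RNG seed (used by the stochastic generators).
#' @param path optional output path (YAML for `edl_1to4`, CSV for
#'   `salt_table`, PQR for `random_charges`).
#' @param n size parameter (atoms for `random_charges`, concentrations for
#'   `salt_table`).
#' @param alpha Born-scaling parameters for `salt_table`.
#' @param spec optional `pnpb_hydration` for `salt_table` (defaults to a
#'   chloride-like ion).
#' @return the generated object; if `path` is given the file is written.
#' @export
generate_fixture <- function(name = c("edl_1to4", "salt_table",
                                      "random_charges", "toy_pocket"),
                             seed = 1, path = NULL, n = 8,
                             alpha = c(0.05, -0.01, 0), spec = NULL) {
  name <- match.arg(name)
  if (name == "edl_1to4") {
    cfg <- list(
      temperature_K = 298.15,
      composition = list(
        list(name = "C+", z = 1, radius_A = 4.65, conc_M = 0.4),
        list(name = "A4-", z = -4, radius_A = 4.65, conc_M = 0.1),
        list(name = "H2O", z = 0, radius_A = 1.4, conc_M = 55.5)),
      domain = list(L = 40, n = 801, sigma = 0.02, eps_s = 80,
                    lc = 1.6 * 4.65))
    if (!is.null(path)) yaml::write_yaml(cfg, path)
    return(cfg)
  }
  if (name == "salt_table") {
    if (is.null(spec))
      spec <- hydration_spec("Cl-", -1, 1.81, 2.266, O_w = 18,
                             alpha = alpha)
    spec$alpha <- alpha
    mk <- binary_salt("X+", spec$name, z = c(1, spec$z),
                      radius_A = c(0.6, spec$a))
    conc <- seq(0.1, 1.6, length.out = n)
    lng <- vapply(conc, function(cc)
      activity_coefficient(spec, mk(cc), "generalized"), numeric(1))
    df <- data.frame(salt = paste0("X", spec$name), conc_M = conc,
                     gamma = exp(lng))
    if (!is.null(path))
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(df)
  }
  if (name == "random_charges") {
    set.seed(seed)
    ch <- point_charges(q = round(stats::runif(n, -1, 1), 4),
                        xyz = matrix(round(stats::runif(3 * n, -10, 10), 3),
                                     n, 3),
                        radius = rep(1.5, n))
    if (!is.null(path)) write_pqr(ch, path)
    return(ch)
  }
  ## toy_pocket: four sites on a 5 A square, unit negative frame charges
  set.seed(seed)
  frame <- point_charges(
    q = rep(-0.5, 4),
    xyz = rbind(c(5, 5, 0), c(-5, 5, 0), c(-5, -5, 0), c(5, -5, 0)))
  sites <- list(
    binding_site(c(2.5, 0, 0), 1.33, 1, 1.5 * sphere_volume(1.33)),
    binding_site(c(-2.5, 0, 0), 1.33, 1, 1.5 * sphere_volume(1.33)),
    binding_site(c(0, 2.5, 0), 0.95, 1, 1.5 * sphere_volume(1.33)),
    binding_site(c(0, -2.5, 0), 0.95, 1, 1.5 * sphere_volume(1.33)))
  list(charges = frame, sites = sites)
}
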