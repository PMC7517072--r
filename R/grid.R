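#' One-dimensional uniform grid
#'
#' @param L domain length in Angstrom.
#' @param n number of nodes (>= 3); spacing `h = L/(n-1)`.
#' @param interfaces optional positions of dielectric interfaces; each must
#'   lie midway between two adjacent nodes.
#' @return object of class `pnpb_grid` with `x`, `h`, `n`, `L`,
#'   `interface_after` (indices i such that the interface lies between
#'   nodes i and i+1).
#' @export
grid1d <- function(L, n, interfaces = NULL) {
  stopifnot(L > 0, n >= 3)
  h <- L / (n - 1)
  x <- seq(0, L, length.out = n)
  idx <- integer(0)
  if (!is.null(interfaces)) {
    mids <- (x[-n] + x[-1]) / 2
    idx <- vapply(interfaces, function(g) {
      i <- which(abs(mids - g) < 1e-9 * max(1, L))
      if (length(i) != 1)
        stop("interface at ", g, " is not midway between adjacent nodes")
      i
    }, integer(1))
  }
  structure(list(x = x, h = h, n = as.integer(n), L = L,
                 interface_after = idx),
            class = "pnpb_grid")
}

## Thomas algorithm for tridiagonal systems; a = sub, b = diag, c = super.
tridiag_solve <- function(a, b, d, rhs) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- d[1] / b[1]; dp[1] <- rhs[1] / b[1]
  for (i in 2:n) {
    m <- b[i] - a[i - 1] * cp[i - 1]
    cp[i] <- if (i < n) d[i] / m else 0
    dp[i] <- (rhs[i] - a[i - 1] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Interface stencil coefficients for a dielectric jump
#'
#' Modified finite-difference coefficients for the 1D equation
#' `-(eps(x) phi'(x))' = f(x)` at an interface lying midway between two
#' adjacent nodes, with material `eps_s` on the left (node i-1 side) and
#' `eps_m` on the right (node i side), and prescribed jumps
#' `jump_phi = phi_right - phi_left` and
#' `jump_flux = (eps phi')_right - (eps phi')_left` at the interface.
#' With equal permittivities and zero jumps the standard central stencil is
#' recovered; the scheme reproduces piecewise-linear solutions exactly and
#' retains second-order convergence for smooth two-material problems.
#'
#' @param eps_m permittivity on the right of the interface.
#' @param eps_s permittivity on the left of the interface.
#' @param jump_phi potential jump (right minus left).
#' @param jump_flux flux jump (right minus left).
#' @param h grid spacing.
#' @return list with coefficients `A1`, `A2`, `A0` (row at the left node)
#'   and `B1`, `B2`, `B0` (row at the right node).
#' @export
interface_stencil <- function(eps_m, eps_s, jump_phi = 0, jump_flux = 0, h = 1) {
  stopifnot(eps_m > 0, eps_s > 0)
  s <- eps_m + eps_s
  A1 <- -(eps_m - eps_s) / s
  A2 <- 2 * eps_m / s
  B1 <- 2 * eps_s / s
  B2 <- (eps_m - eps_s) / s
  A0 <- -(2 * eps_m * jump_phi + h * jump_flux) / s
  B0 <- (2 * eps_s * jump_phi - h * jump_flux) / s
  list(A1 = A1, A2 = A2, A0 = A0, B1 = B1, B2 = B2, B0 = B0)
}

#' Assemble the finite-difference system for -(eps phi')' = f
#'
#' Central second-order finite differences on a uniform grid with Dirichlet
#' or Neumann boundary rows; optional dielectric interfaces (midway between
#' nodes) are discretized with [interface_stencil()]. Neumann conditions
#' prescribe the outward co-normal flux `eps * dphi/dn` and are imposed at
#' second order through ghost-node elimination.
#'
#' @param grid a `pnpb_grid`.
#' @param eps permittivity: scalar or length-n vector (piecewise constant
#'   per region; values at the two nodes flanking an interface are taken as
#'   the two material permittivities).
#' @param f source term, scalar or length-n vector.
#' @param bc list with `left` and `right`, each
#'   `list(type = "dirichlet"|"neumann", value = ...)`.
#' @param jumps optional list per interface with `phi` and `flux` jumps
#'   (right minus left).
#' @return list with sparse matrix `A` (dgCMatrix) and right-hand side `b`;
#'   solve with [poisson_solve()] or `Matrix::solve`.
#' @export
assemble_poisson <- function(grid, eps, f, bc, jumps = NULL) {
  n <- grid$n; h <- grid$h
  eps <- rep_len(eps, n); f <- rep_len(f, n)
  if (bc$left$type == "neumann" && bc$right$type == "neumann")
    stop("gauge error: all-Neumann problem has no unique solution")
  ## edge permittivities (harmonic means reduce to eps for piecewise const)
  em <- 2 * eps[-n] * eps[-1] / (eps[-n] + eps[-1])
  lower <- -em / h^2
  upper <- -em / h^2
  diag0 <- c(em[1], em[-(n - 1)] + em[-1], em[n - 1]) / h^2
  b <- f

  ## interface corrections
  for (k in seq_along(grid$interface_after)) {
    i <- grid$interface_after[k]            # interface between i and i+1
    jp <- if (is.null(jumps)) 0 else jumps[[k]]$phi
    jq <- if (is.null(jumps)) 0 else jumps[[k]]$flux
    epsL <- eps[i]; epsR <- eps[i + 1]
    st <- interface_stencil(eps_m = epsR, eps_s = epsL,
                            jump_phi = jp, jump_flux = jq, h = h)
    ## row at node i (left of interface): coefficients on (i-1, i, i+1)
    lower[i - 1] <- -epsL / h^2
    diag0[i] <- (epsL + (1 - st$A1) * epsL) / h^2
    upper[i] <- -st$A2 * epsL / h^2
    b[i] <- f[i] + epsL * st$A0 / h^2
    ## row at node i+1 (right of interface)
    lower[i] <- -st$B1 * epsR / h^2
    diag0[i + 1] <- ((1 - st$B2) * epsR + epsR) / h^2
    upper[i + 1] <- -epsR / h^2
    b[i + 1] <- f[i + 1] + epsR * st$B0 / h^2
  }

  ## boundary rows
  if (bc$left$type == "dirichlet") {
    diag0[1] <- 1; upper[1] <- 0; b[1] <- bc$left$value
  } else {
    ## eps phi' . n = g with n = -x: ghost elimination, second order
    diag0[1] <- 2 * eps[1] / h^2; upper[1] <- -2 * eps[1] / h^2
    b[1] <- f[1] + 2 * bc$left$value / h
  }
  if (bc$right$type == "dirichlet") {
    diag0[n] <- 1; lower[n - 1] <- 0; b[n] <- bc$right$value
  } else {
    diag0[n] <- 2 * eps[n] / h^2; lower[n - 1] <- -2 * eps[n] / h^2
    b[n] <- f[n] + 2 * bc$right$value / h
  }

  A <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(lower, diag0, upper))
  list(A = methods::as(A, "CsparseMatrix"), b = b,
       tri = list(lower = lower, diag = diag0, upper = upper))
}

#' Solve an assembled 1D Poisson system
#'
#' @param sys result of [assemble_poisson()].
#' @return solution vector `phi`.
#' @export
poisson_solve <- function(sys) {
  tridiag_solve(sys$tri$lower, sys$tri$diag, sys$tri$upper, sys$b)
}
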