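#' Read a PQR point-charge structure
#'
#' Parses the whitespace-delimited PQR variant of the PDB format (as
#' produced by PDB2PQR): `ATOM`/`HETATM` records carrying per-atom charge
#' (e) and radius (Angstrom) in the last two fields. Non-atom records are
#' skipped. A malformed atom record aborts with the offending line number.
#'
#' @param path file path.
#' @return a `pnpb_charges` with radii; atom count and total charge are
#'   reported via `message()`.
#' @export
read_pqr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  if (!any(is_atom)) {
    warning("no atom records in ", path, "; returning an empty charge set")
    return(point_charges(numeric(0), matrix(numeric(0), 0, 3),
                         source = path))
  }
  idx <- which(is_atom)
  n <- length(idx)
  q <- numeric(n); xyz <- matrix(NA_real_, n, 3); rad <- numeric(n)
  for (k in seq_len(n)) {
    tok <- strsplit(trimws(lines[idx[k]]), "[[:space:]]+")[[1]]
    ## record serial name resname [chain] resseq x y z q r
    if (length(tok) < 10)
      stop("malformed PQR atom record at line ", idx[k], ": expected at ",
           "least 10 whitespace-separated fields", call. = FALSE)
    num <- suppressWarnings(as.numeric(tok[(length(tok) - 4):length(tok)]))
    if (any(is.na(num)))
      stop("malformed PQR atom record at line ", idx[k],
           ": non-numeric coordinate/charge/radius fields", call. = FALSE)
    xyz[k, ] <- num[1:3]; q[k] <- num[4]; rad[k] <- num[5]
  }
  message(sprintf("read %d atoms from %s, total charge %.4f e",
                  n, path, sum(q)))
  point_charges(q, xyz, radius = rad, source = path)
}

#' Write a point-charge set as a PQR file
#'
#' @param charges a `pnpb_charges`.
#' @param path output path.
#' @param name atom name used for all records.
#' @return invisibly, the path.
#' @export
write_pqr <- function(charges, path, name = "Q") {
  n <- length(charges$q)
  rad <- if (is.null(charges$radius)) rep(0, n) else charges$radius
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d %-4s %-4sA%4d    %8.3f%8.3f%8.3f%8.4f%8.4f",
            i, name, "RES", 1L,
            charges$xyz[i, 1], charges$xyz[i, 2], charges$xyz[i, 3],
            charges$q[i], rad[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
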