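#' Genomic relationship matrix from biallelic markers
#'
#' Filters markers on minor allele frequency and missing-call rate, mean-imputes
#' remaining missing dosages per marker, column-centers, and forms the
#' VanRaden-style cross-product \eqn{G = W W^T / m_{eff}}.  For 0/1/2 dosage
#' coding \eqn{m_{eff} = 2 \sum_q p_q (1 - p_q)}; for presence/absence 0/1
#' coding \eqn{m_{eff}} is the number of retained markers.  A diagonal jitter
#' is escalated (factor 10 per retry) until the matrix is positive definite.
#'
#' @param markers numeric matrix, lines in rows (rownames are line IDs),
#'   markers in columns, dosages in \{0, 1\} or \{0, 1, 2\}, `NA` for no-calls.
#' @param maf_min minimum minor allele frequency (computed on observed calls);
#'   markers below it are removed.  Default 0.05.
#' @param max_missing maximum tolerated fraction of missing calls per marker.
#'   Default 0.10.
#' @param jitter initial relative diagonal jitter (multiplied by the mean
#'   diagonal of G); escalated up to `1e-4` relative before giving up.
#' @return A symmetric positive-definite matrix with line IDs as dimnames.
#' @export
compute_grm <- function(markers, maf_min = 0.05, max_missing = 0.10,
                        jitter = 1e-8) {
  markers <- as.matrix(markers)
  if (nrow(markers) < 2) stop("need at least 2 lines to build G")
  max_dose <- max(markers, na.rm = TRUE)
  if (!max_dose %in% c(1, 2))
    stop("marker dosages must be coded 0/1 or 0/1/2")
  miss_frac <- colMeans(is.na(markers))
  p <- colMeans(markers, na.rm = TRUE) / max_dose
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= maf_min & miss_frac <= max_missing
  if (!any(keep)) stop("all markers removed by MAF/missingness filters")
  W <- markers[, keep, drop = FALSE]
  p <- p[keep]
  for (q in which(colSums(is.na(W)) > 0)) {
    W[is.na(W[, q]), q] <- mean(W[, q], na.rm = TRUE)
  }
  W <- sweep(W, 2, colMeans(W))
  m_eff <- if (max_dose == 2) 2 * sum(p * (1 - p)) else ncol(W)
  G <- tcrossprod(W) / m_eff
  G <- (G + t(G)) / 2
  base <- mean(diag(G))
  if (base <= 0) base <- 1
  eps <- jitter
  repeat {
    ok <- tryCatch({chol(G); TRUE}, error = function(e) FALSE)
    if (ok) break
    if (eps > 1e-4) stop("G could not be stabilized to positive definite")
    G <- G + diag(eps * base, nrow(G))
    eps <- eps * 10
  }
  rn <- rownames(markers)
  if (!is.null(rn)) dimnames(G) <- list(rn, rn)
  G
}

#' Read marker dosages or a precomputed relationship matrix
#'
#' `load_markers` reads a delimited file whose first column is the line ID and
#' remaining columns are dosages (`NA` or empty for no-calls).  `load_grm`
#' reads a square relationship matrix with line IDs in the first column and as
#' column headers.
#'
#' @param path file path; comma-separated for `.csv`, tab otherwise.
#' @return A numeric matrix with line IDs as rownames.
#' @export
load_markers <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname load_markers
#' @export
load_grm <- function(path) {
  m <- load_markers(path)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(rownames(m), colnames(m))))
    stop("relationship matrix file must be square with matching line IDs")
  if (max(abs(m - t(m))) > 1e-10)
    stop("relationship matrix is not symmetric")
  (m + t(m)) / 2
}

# Align a G matrix to the dataset's line order; identity when G is NULL.
align_grm <- function(G, line_ids) {
  J <- length(line_ids)
  if (is.null(G)) {
    G <- diag(J)
    dimnames(G) <- list(line_ids, line_ids)
    return(G)
  }
  G <- as.matrix(G)
  if (!is.null(rownames(G))) {
    if (!all(line_ids %in% rownames(G)))
      stop("G lacks line(s): ", setdiff(line_ids, rownames(G))[1])
    G <- G[line_ids, line_ids]
  } else if (nrow(G) != J) {
    stop("G dimension ", nrow(G), " does not match ", J, " lines")
  }
  if (max(abs(G - t(G))) > 1e-10) stop("G is not symmetric")
  (G + t(G)) / 2
}
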