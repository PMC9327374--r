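#' Genomic-relationship matrices
#'
#' A `grm_data` object holds the sample identifiers, the symmetric N x N
#' genomic-relationship matrix (GRM) `A`, and the per-pair SNP counts used to
#' compute each entry. GRMs are exchanged on disk in the GCTA binary format
#' (`.grm.bin` / `.grm.N.bin` / `.grm.id`), which is also what PLINK and LDAK
#' emit, so any upstream tool can supply the relatedness input.
#'
#' @param ids data frame (or 2-column matrix) of family and individual
#'   identifiers, one row per sample.
#' @param A symmetric numeric N x N relatedness matrix.
#' @param n_pairs matrix of SNP counts per pair, or a single number when all
#'   pairs use the same M SNPs.
#' @return An object of class `grm_data` with elements `ids` (data frame with
#'   columns `FID`, `IID`), `A`, and `n_pairs`.
#' @export
grm_data <- function(ids, A, n_pairs = NA_real_) {
  ids <- .as_id_frame(ids)
  n <- nrow(ids)
  A <- as.matrix(A)
  if (!is.numeric(A) || nrow(A) != n || ncol(A) != n)
    stop("'A' must be a numeric ", n, " x ", n, " matrix matching 'ids'")
  if (anyDuplicated(.id_key(ids)))
    stop("duplicate (FID, IID) pairs in GRM ids")
  if (!anyNA(A) && max(abs(A - t(A))) > 1e-6 * max(1, max(abs(A))))
    stop("'A' is not symmetric")
  A <- (A + t(A)) / 2
  if (length(n_pairs) == 1L) n_pairs <- matrix(as.numeric(n_pairs), n, n)
  if (!all(dim(n_pairs) == c(n, n)))
    stop("'n_pairs' must be scalar or have the same dimensions as 'A'")
  structure(list(ids = ids, A = A, n_pairs = n_pairs), class = "grm_data")
}

#' @export
print.grm_data <- function(x, ...) {
  n <- nrow(x$ids)
  cat("Genomic-relationship matrix:", n, "individuals\n")
  cat("  mean diagonal:", format(mean(diag(x$A)), digits = 4),
      " mean off-diagonal:",
      format((sum(x$A) - sum(diag(x$A))) / (n * (n - 1)), digits = 4), "\n")
  invisible(x)
}

.as_id_frame <- function(ids) {
  ids <- as.data.frame(ids, stringsAsFactors = FALSE)
  if (ncol(ids) < 2L) stop("ids must have two columns (FID, IID)")
  ids <- ids[, 1:2]
  names(ids) <- c("FID", "IID")
  ids$FID <- as.character(ids$FID)
  ids$IID <- as.character(ids$IID)
  rownames(ids) <- NULL
  ids
}

# exact, case-sensitive join key on (FID, IID)
.id_key <- function(ids) paste(ids$FID, ids$IID, sep = "\r")

# row/column positions of the packed lower triangle (diagonal included),
# stored row-major as in GCTA: (1,1), (2,1), (2,2), (3,1), ...
.tri_index <- function(n) {
  list(row = rep.int(seq_len(n), seq_len(n)), col = sequence(seq_len(n)))
}

#' Read a GRM in GCTA binary format
#'
#' Reads the triple `prefix.grm.bin` (packed lower triangle including the
#' diagonal, row-major, little-endian 32-bit floats), `prefix.grm.N.bin`
#' (matching per-pair SNP counts, same packing) and `prefix.grm.id`
#' (tab-delimited FID / IID, one line per individual).
#'
#' @param prefix path prefix of the GRM file triple.
#' @return A [grm_data] object.
#' @export
read_grm <- function(prefix) {
  f_bin <- paste0(prefix, ".grm.bin")
  f_n <- paste0(prefix, ".grm.N.bin")
  f_id <- paste0(prefix, ".grm.id")
  if (!file.exists(f_id)) stop("missing GRM id file: ", f_id)
  if (!file.exists(f_bin)) stop("missing GRM file: ", f_bin)
  ids <- utils::read.table(f_id, header = FALSE, sep = "\t",
                           colClasses = "character")
  ids <- .as_id_frame(ids)
  n <- nrow(ids)
  if (anyDuplicated(.id_key(ids)))
    stop("duplicate (FID, IID) pairs in ", f_id)
  n_tri <- n * (n + 1) / 2
  if (file.size(f_bin) != 4 * n_tri)
    stop("GRM format error: ", f_bin, " holds ", file.size(f_bin),
         " bytes but ", n, " ids imply ", 4 * n_tri)
  tri <- readBin(f_bin, what = "numeric", n = n_tri, size = 4L,
                 endian = "little")
  idx <- .tri_index(n)
  A <- matrix(0, n, n)
  A[cbind(idx$row, idx$col)] <- tri
  A[cbind(idx$col, idx$row)] <- tri
  n_pairs <- NA_real_
  if (file.exists(f_n)) {
    sz <- file.size(f_n)
    if (sz == 4) {
      n_pairs <- readBin(f_n, "numeric", n = 1L, size = 4L, endian = "little")
    } else if (sz == 4 * n_tri) {
      cnt <- readBin(f_n, "numeric", n = n_tri, size = 4L, endian = "little")
      n_pairs <- matrix(0, n, n)
      n_pairs[cbind(idx$row, idx$col)] <- cnt
      n_pairs[cbind(idx$col, idx$row)] <- cnt
    } else {
      stop("GRM format error: ", f_n, " size matches neither 1 nor ",
           n_tri, " float32 values")
    }
  }
  grm_data(ids, A, n_pairs)
}

#' Write a GRM in GCTA binary format
#'
#' @param grm a [grm_data] object.
#' @param prefix output path prefix; the files `prefix.grm.bin`,
#'   `prefix.grm.N.bin` and `prefix.grm.id` are (over)written.
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm_data"))
  n <- nrow(grm$ids)
  idx <- .tri_index(n)
  tri <- grm$A[cbind(idx$row, idx$col)]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(tri, con, size = 4L, endian = "little")
  close(con)
  cnt <- grm$n_pairs[cbind(idx$row, idx$col)]
  cnt[is.na(cnt)] <- 0
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(cnt, con, size = 4L, endian = "little")
  close(con)
  utils::write.table(grm$ids, paste0(prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Compute a GRM from standardized genotypes
#'
#' The GRM of N individuals over M standardized SNPs is `A = G G' / M`: the
#' average over SNPs of products of standardized genotypes, so that the mean
#' diagonal is approximately 1 when columns are standardized with in-sample
#' allele frequencies.
#'
#' @param G numeric N x M matrix of standardized genotypes (each column mean 0,
#'   variance 1; see [standardize_genotypes] for raw 0/1/2 counts).
#' @param ids sample identifiers, as in [grm_data].
#' @return A [grm_data] object with `n_pairs` equal to M for every pair.
#' @export
compute_grm <- function(G, ids) {
  G <- as.matrix(G)
  m <- ncol(G)
  if (m == 0L) stop("no SNPs: 'G' has zero columns")
  grm_data(ids, tcrossprod(G) / m, n_pairs = m)
}

#' Standardize raw genotype counts
#'
#' Columns holding minor-allele counts 0/1/2 are centred at `2 p` and scaled by
#' `sqrt(2 p (1 - p))`, with `p` the in-sample allele frequency. Monomorphic
#' columns (`p` of 0 or 1) carry no information and are dropped.
#'
#' @param G012 numeric N x M matrix of allele counts in \{0, 1, 2\}.
#' @return Standardized genotype matrix with monomorphic columns removed.
#' @export
standardize_genotypes <- function(G012) {
  G012 <- as.matrix(G012)
  p <- colMeans(G012) / 2
  keep <- p > 0 & p < 1
  G <- G012[, keep, drop = FALSE]
  p <- p[keep]
  sweep(sweep(G, 2L, 2 * p, "-"), 2L, sqrt(2 * p * (1 - p)), "/")
}
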