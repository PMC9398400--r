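#' Built-in RVD-base preference matrix
#'
#' Preferences quantify, on a 0..1 scale, how well each RVD tolerates
#' each base at its repeat position. The built-in default is derived from
#' the canonical code: the cognate base of each RVD (HD:C, NN:G, NI:A,
#' NG:T) gets 1.0, NN's weaker second preference for A gets 0.6, and all
#' other combinations get 0.0. Published quantitative preference tables
#' (e.g. from SELEX binding or activation data) can be substituted via
#' [load_preference_matrix()] without code changes.
#'
#' @return Numeric matrix (rows = RVDs, columns = A,C,G,T) with class
#'   `"preference_matrix"` and a `provenance` attribute.
#' @export
default_preference_matrix <- function() {
  m <- matrix(0, nrow = 4L, ncol = 4L,
              dimnames = list(c("HD", "NN", "NI", "NG"), DNA_BASES))
  m["HD", "C"] <- 1
  m["NN", "G"] <- 1
  m["NN", "A"] <- 0.6
  m["NI", "A"] <- 1
  m["NG", "T"] <- 1
  structure(m, provenance = "builtin canonical code default",
            class = c("preference_matrix", "matrix", "array"))
}

# shared validation for built-in and file-loaded matrices
validate_preference_matrix <- function(m, provenance = "user") {
  if (!is.matrix(m) || !is.numeric(m)) {
    ot_stop("matrix", "preference matrix must be a numeric matrix")
  }
  if (!identical(colnames(m), DNA_BASES)) {
    ot_stop("matrix", sprintf(
      "preference matrix columns must be exactly A, C, G, T (got: %s)",
      paste(colnames(m), collapse = ", ")))
  }
  if (anyNA(m)) ot_stop("matrix", "preference matrix has missing cells")
  if (any(m < 0 | m > 1)) {
    ot_stop("range", "preference values must lie in [0, 1]")
  }
  for (rvd in intersect(rownames(m), names(RVD_PREFERRED_BASE))) {
    cognate <- RVD_PREFERRED_BASE[[rvd]]
    if (m[rvd, cognate] < max(m[rvd, ])) {
      ot_stop("matrix", sprintf(
        "cognate base %s of RVD %s is not the row maximum", cognate, rvd))
    }
  }
  structure(m, provenance = provenance,
            class = c("preference_matrix", "matrix", "array"))
}

#' Load an RVD-base preference matrix from TSV
#'
#' Expected dialect: tab-separated, header `RVD\tA\tC\tG\tT`, one row per
#' RVD, '.' decimal separator, UTF-8. Values must lie in \[0, 1\] and the
#' cognate base of each canonical RVD must be its row maximum.
#'
#' @param path TSV path; `NULL` returns [default_preference_matrix()].
#' @return A `"preference_matrix"`.
#' @export
load_preference_matrix <- function(path = NULL) {
  if (is.null(path)) return(default_preference_matrix())
  if (!file.exists(path)) ot_stop("io", sprintf("file not found: %s", path))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(colnames(df)[1L], "RVD")) {
    ot_stop("matrix", "first TSV column must be named 'RVD'")
  }
  extra <- setdiff(colnames(df)[-1L], DNA_BASES)
  if (length(extra) > 0L) {
    ot_stop("matrix", sprintf("unknown base column(s): %s",
                              paste(extra, collapse = ", ")))
  }
  if (!all(DNA_BASES %in% colnames(df))) {
    ot_stop("matrix", "TSV must have one column per base A, C, G, T")
  }
  m <- as.matrix(df[, DNA_BASES, drop = FALSE])
  if (!is.numeric(m)) ot_stop("matrix", "non-numeric preference cell")
  rownames(m) <- df$RVD
  validate_preference_matrix(m, provenance = path)
}

#' Write a preference matrix as TSV
#'
#' @param matrix A `"preference_matrix"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_preference_matrix <- function(matrix, path) {
  df <- data.frame(RVD = rownames(matrix), unclass(matrix)[, DNA_BASES],
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.preference_matrix <- function(x, ...) {
  cat(sprintf("<RVD-base preference matrix> (%s)\n", attr(x, "provenance")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Mismatch score S_M for one RVD-base pairing
#'
#' `S_M = (preference - 0.5) * (-2)`: an affine, strictly decreasing map
#' of the preference onto \[-1, 1\]. A fully disfavored base (preference
#' 0) scores +1, a cognate base (preference 1) scores -1, and a neutral
#' base (preference 0.5) scores 0. Higher S_M means the mismatch is more
#' disruptive to binding — safer for orthogonality.
#'
#' @param matrix A `"preference_matrix"`.
#' @param rvd RVD code (row of `matrix`).
#' @param base Genomic base at the mismatch ("A","C","G","T").
#' @return Numeric S_M in \[-1, 1\].
#' @export
mismatch_score <- function(matrix, rvd, base) {
  if (!rvd %in% rownames(matrix)) {
    ot_stop("rvd", sprintf("RVD '%s' not in preference matrix", rvd))
  }
  if (!base %in% colnames(matrix)) {
    ot_stop("base", sprintf("base '%s' not in preference matrix", base))
  }
  (matrix[rvd, base] - 0.5) * -2
}

#' Position factor F_P
#'
#' `F_P = 1 / sqrt(position)`, positions 1-based with T0 at position 1.
#' Strictly decreasing: T0-proximal mismatches are less tolerated by the
#' TALE than T0-distal ones, so proximal mismatches carry more weight.
#'
#' @param position Integer vector of 1-based mismatch positions.
#' @return Numeric vector of weights in (0, 1].
#' @examples
#' position_factor(c(1, 4, 9)) # 1, 0.5, 1/3
#' @export
position_factor <- function(position) {
  if (length(position) == 0L) return(numeric(0L))
  if (any(!is.finite(position)) || any(position < 1)) {
    ot_stop("position", "mismatch positions must be >= 1")
  }
  1 / sqrt(position)
}
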