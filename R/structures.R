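#' Backbone stretch and structure containers
#'
#' A `cv_stretch` holds one connected run of residues in which all four
#' main-chain atoms (N, CA, C, O) are present and every consecutive pair
#' passes the C--N peptide-bond distance test. A `cv_structure` is a list of
#' such stretches plus provenance. Coordinates are stored as one n x 3
#' matrix per atom type so that all vector geometry is plain matrix algebra.
#'
#' @param chain chain identifier (single string)
#' @param resno integer residue numbers (author numbering)
#' @param resname three-letter residue codes
#' @param xyz named list of n x 3 matrices for N, CA, C and O
#' @param ins insertion codes (single characters, "" when absent)
#' @param b n x 4 matrix of per-atom B factors (columns N, CA, C, O)
#' @param sg n x 3 matrix of S-gamma coordinates (rows NA when absent)
#' @param provenance list with source file, model index and chain
#' @return an object of class `cv_stretch`
#' @export
new_stretch <- function(chain, resno, resname, xyz, ins = NULL, b = NULL,
                        sg = NULL, provenance = list()) {
  n <- length(resno)
  stopifnot(n >= 1, all(c("N", "CA", "C", "O") %in% names(xyz)))
  for (nm in c("N", "CA", "C", "O")) {
    xyz[[nm]] <- matrix(as.numeric(xyz[[nm]]), ncol = 3)
    stopifnot(nrow(xyz[[nm]]) == n, all(is.finite(xyz[[nm]])))
  }
  if (is.null(ins)) ins <- rep("", n)
  if (is.null(b)) b <- matrix(20, n, 4)
  if (is.null(sg)) sg <- matrix(NA_real_, n, 3)
  structure(list(chain = chain, resno = as.integer(resno), ins = ins,
                 resname = resname, xyz = xyz[c("N", "CA", "C", "O")],
                 b = b, sg = sg, provenance = provenance),
            class = "cv_stretch")
}

#' @param stretches list of `cv_stretch`
#' @param source path of the originating file (or a label)
#' @param model model index
#' @rdname new_stretch
#' @export
new_structure <- function(stretches, source = "memory", model = 0L) {
  stopifnot(length(stretches) >= 1)
  structure(list(stretches = stretches, source = source, model = model),
            class = "cv_structure")
}

#' @export
print.cv_stretch <- function(x, ...) {
  cat(sprintf("<cv_stretch> chain %s, %d residues (%d-%d)\n",
              x$chain, length(x$resno), x$resno[1], x$resno[length(x$resno)]))
  invisible(x)
}

#' @export
print.cv_structure <- function(x, ...) {
  cat(sprintf("<cv_structure> %s (model %d): %d stretch(es), %d residues\n",
              x$source, x$model, length(x$stretches),
              sum(vapply(x$stretches, function(s) length(s$resno), 1L))))
  invisible(x)
}

#' @export
length.cv_stretch <- function(x) length(x$resno)

# Number of residues across all stretches.
n_residues <- function(structure) {
  sum(vapply(structure$stretches, length, 1L))
}

# Apply a rigid transform to every atom of a stretch / structure.
transform_stretch <- function(stretch, R = diag(3), t = c(0, 0, 0)) {
  stretch$xyz <- lapply(stretch$xyz, transform_xyz, R = R, t = t)
  ok <- !is.na(stretch$sg[, 1])
  if (any(ok)) stretch$sg[ok, ] <- transform_xyz(stretch$sg[ok, , drop = FALSE], R, t)
  stretch
}

#' Apply a rigid motion to a whole structure
#'
#' @param structure a `cv_structure`
#' @param R 3x3 rotation matrix
#' @param t translation 3-vector in Angstrom
#' @return the transformed `cv_structure`
#' @export
transform_structure <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  structure$stretches <- lapply(structure$stretches, transform_stretch, R = R, t = t)
  structure
}
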