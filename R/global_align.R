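# Needleman-Wunsch global alignment with affine gap penalties (Gotoh
# three-state dynamic programme) and percent identity over the full
# alignment length. The default scoring matches the NCBI global-alignment
# tool defaults for proteins: BLOSUM62, gap existence 11, extension 1
# (a gap of length L costs 11 + L).

aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M", "F",
    "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "*")
}

blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Needleman-Wunsch global alignment with affine gaps
#'
#' Gotoh's three-state dynamic programme maximising the substitution score
#' minus affine gap costs (`gap_open + gap_extend * length` per gap).
#' Traceback ties prefer substitution over a gap, then a gap in `a`.
#' Percent identity is `100 * matches / alignment_length`, counting gap
#' columns in the denominator (NCBI convention).
#'
#' @param a,b amino-acid sequences (character scalars).
#' @param substitution substitution matrix (default BLOSUM62); rows and
#'   columns named by residue.
#' @param gap_open gap existence cost (11).
#' @param gap_extend per-residue gap extension cost (1).
#' @return an `alignment_result` list: `aligned_a`, `aligned_b`, `score`,
#'   `matches`, `alignment_length`, `percent_identity`.
#' @export
needleman_wunsch <- function(a, b, substitution = NULL, gap_open = 11,
                             gap_extend = 1) {
  if (is.null(substitution)) substitution <- blosum62_matrix()
  sa <- strsplit(toupper(a), "")[[1L]]
  sb <- strsplit(toupper(b), "")[[1L]]
  for (nm in c("a", "b")) {
    s <- if (nm == "a") sa else sb
    bad <- which(!s %in% rownames(substitution))
    if (length(bad)) {
      stop(sprintf("invalid residue '%s' at position %d of sequence %s",
                   s[bad[1L]], bad[1L], nm))
    }
  }
  n <- length(sa); m <- length(sb)
  NEG <- -1e9
  gap1 <- gap_open + gap_extend  # cost of opening a length-1 gap
  # M: a[i] aligned to b[j]; X: gap in b (a[i] over '-'); Y: gap in a
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in 2L:(n + 1L)) X[i, 1L] <- -(gap_open + gap_extend * (i - 1L))
  for (j in 2L:(m + 1L)) Y[1L, j] <- -(gap_open + gap_extend * (j - 1L))
  sub <- substitution[sa, sb, drop = FALSE]
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- sub[i - 1L, j - 1L]
      M[i, j] <- s + max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                         Y[i - 1L, j - 1L])
      X[i, j] <- max(M[i - 1L, j] - gap1, X[i - 1L, j] - gap_extend,
                     Y[i - 1L, j] - gap1)
      Y[i, j] <- max(M[i, j - 1L] - gap1, Y[i, j - 1L] - gap_extend,
                     X[i, j - 1L] - gap1)
    }
  }
  finals <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  score <- max(finals)
  state <- which.max(finals)  # tie-break: M, then X (gap in b), then Y
  ai <- character(0); bi <- character(0)
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      ai <- c(sa[i - 1L], ai); bi <- c(sb[j - 1L], bi)
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      target <- M[i, j] - sub[i - 1L, j - 1L]
      state <- which(abs(prev - target) < 1e-9)[1L]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      ai <- c(sa[i - 1L], ai); bi <- c("-", bi)
      if (i == 2L && j == 1L) { i <- 1L; break }
      cand <- c(M[i - 1L, j] - gap1, X[i - 1L, j] - gap_extend,
                Y[i - 1L, j] - gap1)
      state <- which(abs(cand - X[i, j]) < 1e-9)[1L]
      i <- i - 1L
    } else {
      ai <- c("-", ai); bi <- c(sb[j - 1L], bi)
      if (j == 2L && i == 1L) { j <- 1L; break }
      cand <- c(M[i, j - 1L] - gap1, Y[i, j - 1L] - gap_extend,
                X[i, j - 1L] - gap1)
      state <- c(1L, 3L, 2L)[which(abs(cand - Y[i, j]) < 1e-9)[1L]]
      j <- j - 1L
    }
    if (i == 1L && j > 1L) state <- 3L
    if (j == 1L && i > 1L) state <- 2L
  }
  len <- length(ai)
  matches <- sum(ai == bi & ai != "-")
  structure(list(aligned_a = paste(ai, collapse = ""),
                 aligned_b = paste(bi, collapse = ""),
                 score = score, matches = matches, alignment_length = len,
                 percent_identity = 100 * matches / len),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("Global alignment: score %g, identity %d/%d (%.1f%%)\n",
              x$score, x$matches, x$alignment_length, x$percent_identity))
  cat(x$aligned_a, "\n")
  cat(paste(ifelse(strsplit(x$aligned_a, "")[[1L]] ==
                     strsplit(x$aligned_b, "")[[1L]], "|", " "),
            collapse = ""), "\n")
  cat(x$aligned_b, "\n")
  invisible(x)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}

#' The bundled prosurfactant protein C propeptide pair
#'
#' Returns the mouse (UniProt P21841) and human (UniProt P11686) pulmonary
#' surfactant-associated protein C propeptide residues 1-100 shipped with
#' the package.
#'
#' @return named character vector of the two sequences.
#' @export
prospc_propeptides <- function() {
  read_fasta_sequences(system.file("extdata", "prospc_propeptide_1-100.fasta",
                                   package = "cytovol3d", mustWork = TRUE))
}
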