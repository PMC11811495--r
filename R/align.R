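#' Scoring scheme for local alignment
#'
#' Bundles a substitution matrix with affine gap penalties. A gap run of
#' length \eqn{k} costs \code{gap_open + k * gap_extend} (the opening penalty
#' is charged once per run, the extension penalty per gapped position).
#'
#' @param substitution Square numeric matrix with identical row and column
#'   names (the residue alphabet).
#' @param gap_open Gap-opening penalty, a non-positive number.
#' @param gap_extend Per-position gap-extension penalty, non-positive.
#' @param name Label recorded in alignment output metadata.
#' @return An object of class \code{scoring_scheme}.
#' @export
scoring_scheme <- function(substitution, gap_open, gap_extend,
                           name = "custom") {
  if (!is.matrix(substitution) || is.null(rownames(substitution)) ||
      !identical(rownames(substitution), colnames(substitution)))
    stop("substitution must be a square matrix with matching dimnames",
         call. = FALSE)
  if (gap_open > 0 || gap_extend > 0)
    stop("gap penalties must be non-positive", call. = FALSE)
  structure(list(substitution = substitution,
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend),
                 alphabet = rownames(substitution),
                 name = name),
            class = "scoring_scheme")
}

#' Simple nucleotide scoring scheme
#'
#' Match/mismatch scoring over \{A, C, G, T\}.
#'
#' @param match Match score (default +1).
#' @param mismatch Mismatch score (default -1).
#' @param gap_open,gap_extend Affine gap penalties (defaults -2 and -1).
#' @return A \code{scoring_scheme}.
#' @export
nucleotide_scheme <- function(match = 1, mismatch = -1,
                              gap_open = -2, gap_extend = -1) {
  nt <- c("A", "C", "G", "T")
  sub <- matrix(mismatch, 4L, 4L, dimnames = list(nt, nt))
  diag(sub) <- match
  scoring_scheme(sub, gap_open, gap_extend,
                 name = sprintf("nt(match=%g,mismatch=%g)", match, mismatch))
}

#' BLOSUM62 protein scoring scheme
#'
#' The standard BLOSUM62 matrix with affine gap penalties, the conventional
#' default for protein similarity searches.
#'
#' @param gap_open,gap_extend Affine gap penalties (defaults -10 and -1).
#' @return A \code{scoring_scheme}.
#' @export
protein_scheme <- function(gap_open = -10, gap_extend = -1) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  scoring_scheme(env$BLOSUM62, gap_open, gap_extend, name = "BLOSUM62")
}

#' Smith-Waterman local alignment
#'
#' Affine-gap local alignment (Gotoh formulation) with a score floor of
#' zero. Identity is computed from one optimal traceback (ties broken by
#' preferring diagonal, then gap-in-\code{b}, moves) as the number of
#' identical columns divided by the total number of alignment columns,
#' gap columns included. A score of zero yields an empty alignment and
#' identity 0.
#'
#' @param a,b Residue strings over the scheme's alphabet.
#' @param scheme A \code{\link{scoring_scheme}}.
#' @return List with elements \code{score}, \code{identity},
#'   \code{aligned_a}, \code{aligned_b} (gapped aligned substrings, gaps as
#'   \code{"-"}), \code{length} (alignment columns) and \code{scheme} (the
#'   scheme name).
#' @export
smith_waterman <- function(a, b, scheme = nucleotide_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  av <- check_residues(a, scheme$alphabet, "a")
  bv <- check_residues(b, scheme$alphabet, "b")
  n <- length(av); m <- length(bv)
  empty <- list(score = 0, identity = 0, aligned_a = "", aligned_b = "",
                length = 0L, scheme = scheme$name)
  if (n == 0L || m == 0L) return(empty)

  sub <- scheme$substitution
  go <- scheme$gap_open; ge <- scheme$gap_extend
  neg <- -Inf
  H <- matrix(0, n + 1L, m + 1L)   # best local score ending at (i, j)
  E <- matrix(neg, n + 1L, m + 1L) # ending with a gap in a (consumes b[j])
  F <- matrix(neg, n + 1L, m + 1L) # ending with a gap in b (consumes a[i])
  ai <- match(av, scheme$alphabet)
  bi <- match(bv, scheme$alphabet)
  for (i in seq_len(n)) {
    srow <- sub[ai[i], ]
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] + go + ge, E[i + 1L, j] + ge)
      F[i + 1L, j + 1L] <- max(H[i, j + 1L] + go + ge, F[i, j + 1L] + ge)
      H[i + 1L, j + 1L] <- max(0,
                               H[i, j] + srow[bi[j]],
                               E[i + 1L, j + 1L],
                               F[i + 1L, j + 1L])
    }
  }
  best <- max(H)
  if (best <= 0) return(empty)

  # traceback from the first (row-major) maximal cell
  idx <- which(H == best, arr.ind = TRUE)
  i <- idx[1L, 1L]; j <- idx[1L, 2L]
  cols_a <- character(0L); cols_b <- character(0L)
  state <- "H"
  while (!(state == "H" && H[i, j] == 0)) {
    if (state == "H") {
      diag_score <- if (i > 1L && j > 1L)
        H[i - 1L, j - 1L] + sub[ai[i - 1L], bi[j - 1L]] else neg
      if (i > 1L && j > 1L && H[i, j] == diag_score) {
        cols_a <- c(av[i - 1L], cols_a); cols_b <- c(bv[j - 1L], cols_b)
        i <- i - 1L; j <- j - 1L
      } else if (H[i, j] == F[i, j]) {
        state <- "F"
      } else {
        state <- "E"
      }
    } else if (state == "F") { # gap in b, consumes a[i-1]
      cols_a <- c(av[i - 1L], cols_a); cols_b <- c("-", cols_b)
      from_open <- H[i - 1L, j] + go + ge
      state <- if (F[i, j] == from_open) "H" else "F"
      i <- i - 1L
    } else {                   # gap in a, consumes b[j-1]
      cols_a <- c("-", cols_a); cols_b <- c(bv[j - 1L], cols_b)
      from_open <- H[i, j - 1L] + go + ge
      state <- if (E[i, j] == from_open) "H" else "E"
      j <- j - 1L
    }
  }
  len <- length(cols_a)
  ident <- sum(cols_a == cols_b & cols_a != "-") / len
  list(score = best, identity = ident,
       aligned_a = paste(cols_a, collapse = ""),
       aligned_b = paste(cols_b, collapse = ""),
       length = len, scheme = scheme$name)
}

check_residues <- function(x, alphabet, arg) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("sequence '", arg, "' must be a single string", call. = FALSE)
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  bad <- which(!(v %in% alphabet))
  if (length(bad))
    stop("symbol '", v[bad[1L]], "' at position ", bad[1L], " of sequence '",
         arg, "' is not in the scoring alphabet", call. = FALSE)
  v
}

#' Build a best-similarity table from sequences
#'
#' Computes Smith-Waterman score and identity for every gene of the target
#' species against every sequence from other species, producing the
#' five-column record format consumed by \code{\link{filter_homologs}} and
#' \code{\link{pai_bst}}. Intended for small sequence sets; the alignment is
#' quadratic in sequence length.
#'
#' @param sequences Named character vector of residue strings; names follow
#'   the \code{"species_code|gene_id"} convention.
#' @param target Species code whose genes are the queries.
#' @param scheme A \code{\link{scoring_scheme}}.
#' @return Data frame of similarity records (one row per query/subject
#'   pair), plus a \code{scheme} attribute naming the scoring scheme.
#' @export
build_similarity_table <- function(sequences, target,
                                   scheme = protein_scheme()) {
  ids <- strsplit(names(sequences), "|", fixed = TRUE)
  if (any(lengths(ids) != 2L))
    stop("sequence names must follow 'species_code|gene_id'", call. = FALSE)
  species <- vapply(ids, `[`, character(1L), 1L)
  genes <- vapply(ids, `[`, character(1L), 2L)
  qi <- which(species == target)
  si <- which(species != target)
  out <- vector("list", length(qi) * length(si))
  k <- 0L
  for (q in qi) for (s in si) {
    aln <- smith_waterman(sequences[[q]], sequences[[s]], scheme)
    k <- k + 1L
    out[[k]] <- data.frame(query_gene = genes[q], subject_gene = genes[s],
                           subject_species = species[s],
                           identity = aln$identity, sw_score = aln$score,
                           stringsAsFactors = FALSE)
  }
  res <- if (k) do.call(rbind, out) else
    data.frame(query_gene = character(0), subject_gene = character(0),
               subject_species = character(0), identity = numeric(0),
               sw_score = numeric(0))
  attr(res, "scheme") <- scheme$name
  res
}
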