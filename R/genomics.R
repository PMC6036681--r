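# Comparative locus arithmetic: pairwise local protein alignment, the
# identity/coverage orthology rule, average amino acid identity (AAI) between
# loci, and locus-versus-genome G+C deviation.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

#' Create a validated protein record
#'
#' @param id record identifier.
#' @param sequence amino-acid string over the 20-letter alphabet plus `X`.
#' @return An object of class `protein_record` (a list with `id`,
#'   `sequence`).
#' @export
protein_record <- function(id, sequence) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("empty protein sequence for '", id, "'")
  letters_used <- unique(strsplit(sequence, "")[[1]])
  bad <- setdiff(letters_used, c(AA_ALPHABET, "X"))
  if (length(bad))
    stop("invalid amino-acid letter(s) in '", id, "': ", paste(bad, collapse = ""))
  structure(list(id = as.character(id), sequence = sequence),
            class = "protein_record")
}

as_protein <- function(x, id = "seq") {
  if (inherits(x, "protein_record")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (!is.null(names(x))) id <- names(x)
    return(protein_record(id, x))
  }
  stop("expected a protein_record or a single character string")
}

as_protein_list <- function(x, prefix = "seq") {
  if (inherits(x, "protein_record")) return(list(x))
  if (is.character(x)) {
    ids <- if (is.null(names(x))) paste0(prefix, seq_along(x)) else names(x)
    return(mapply(protein_record, ids, x, SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
  lapply(x, as_protein)
}

#' Local pairwise protein alignment
#'
#' Smith-Waterman local alignment with affine gaps under BLAST-like defaults
#' (BLOSUM62, gap open 11, gap extend 1; a gap of length L costs
#' `gap_open + L * gap_extend`), computed with
#' [Biostrings::pairwiseAlignment()]. Identity is the percentage of aligned
#' residue pairs (gap columns excluded from both numerator and denominator)
#' that are identical; coverage is the fraction of a sequence's residues
#' inside the locally aligned region. Two sequences with no positive-scoring
#' residue pair yield the empty alignment: score 0, identity 0, coverage 0.
#'
#' @param a,b query and subject: [protein_record()]s or plain strings.
#' @param matrix substitution matrix name (any matrix shipped with
#'   Biostrings, default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return An object of class `protein_alignment`: `query`, `subject`,
#'   `score`, `identity_pct`, `query_coverage`, `subject_coverage`,
#'   `aligned_query`, `aligned_subject`.
#' @examples
#' local_align("HEAGAWGHEE", "PAWHEAE")
#' @export
local_align <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                        gap_extend = 1) {
  a <- as_protein(a, "query"); b <- as_protein(b, "subject")
  submat <- get_submatrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$sequence), Biostrings::AAString(b$sequence),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  qa <- as.character(Biostrings::pattern(pa))
  sa <- as.character(Biostrings::subject(pa))
  qc <- strsplit(qa, "")[[1]]; sc <- strsplit(sa, "")[[1]]
  paired <- qc != "-" & sc != "-"
  n_pairs <- sum(paired)
  identity <- if (n_pairs) 100 * sum(qc[paired] == sc[paired]) / n_pairs else 0
  structure(list(
    query = a$id, subject = b$id,
    score = BiocGenerics::score(pa),
    identity_pct = identity,
    query_coverage = sum(qc != "-") / nchar(a$sequence),
    subject_coverage = sum(sc != "-") / nchar(b$sequence),
    aligned_query = qa, aligned_subject = sa),
    class = "protein_alignment")
}

get_submatrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("%s vs %s: score %.0f, identity %.2f%%, coverage q %.2f / s %.2f\n",
              x$query, x$subject, x$score, x$identity_pct,
              x$query_coverage, x$subject_coverage))
  if (nzchar(x$aligned_query))
    cat("  ", x$aligned_query, "\n  ", x$aligned_subject, "\n", sep = "")
  invisible(x)
}

#' Apply the orthology decision rule
#'
#' Two proteins are called orthologous when they share strictly more than
#' `identity_threshold` percent amino acid identity over at least
#' `coverage_threshold` sequence coverage. Coverage is assessed on the query
#' by default; set `require_both` to demand it of both sequences.
#'
#' @param alignment a [local_align()] result.
#' @param identity_threshold percent identity that must be exceeded
#'   (default 30; exactly 30% is *not* orthologous).
#' @param coverage_threshold minimum aligned fraction (default 0.70).
#' @param require_both require the coverage of subject as well as query.
#' @return An object of class `orthology_call` with `is_ortholog`, the
#'   thresholds used, and the alignment.
#' @export
is_ortholog <- function(alignment, identity_threshold = 30,
                        coverage_threshold = 0.70, require_both = FALSE) {
  stopifnot(inherits(alignment, "protein_alignment"))
  cov_ok <- alignment$query_coverage >= coverage_threshold &&
    (!require_both || alignment$subject_coverage >= coverage_threshold)
  structure(list(
    query = alignment$query, subject = alignment$subject,
    alignment = alignment,
    is_ortholog = alignment$identity_pct > identity_threshold && cov_ok,
    identity_threshold = identity_threshold,
    coverage_threshold = coverage_threshold,
    require_both = require_both),
    class = "orthology_call")
}

#' @export
print.orthology_call <- function(x, ...) {
  cat(sprintf("%s vs %s: %s (identity %.2f%% %s %g%%, coverage %.2f %s %.2f)\n",
              x$query, x$subject,
              if (x$is_ortholog) "ortholog" else "not ortholog",
              x$alignment$identity_pct,
              if (x$alignment$identity_pct > x$identity_threshold) ">" else "<=",
              x$identity_threshold, x$alignment$query_coverage,
              if (x$alignment$query_coverage >= x$coverage_threshold) ">=" else "<",
              x$coverage_threshold))
  invisible(x)
}

#' Reciprocal-best-hit ortholog pairs between two loci
#'
#' Aligns every protein of locus A against every protein of locus B, keeps
#' pairs that are mutually best-scoring (ties broken by lexicographic id
#' order), and applies the orthology rule to each retained pair. Each protein
#' appears in at most one pair.
#'
#' @param locusA,locusB lists of [protein_record()]s or named character
#'   vectors of sequences.
#' @param ... thresholds passed to [is_ortholog()].
#' @param matrix,gap_open,gap_extend alignment settings, see [local_align()].
#' @return A data.frame with one row per mutual-best pair: `query`,
#'   `subject`, `score`, `identity_pct`, `query_coverage`,
#'   `subject_coverage`, `is_ortholog`.
#' @export
reciprocal_best_pairs <- function(locusA, locusB, matrix = "BLOSUM62",
                                  gap_open = 11, gap_extend = 1, ...) {
  A <- as_protein_list(locusA, "a"); B <- as_protein_list(locusB, "b")
  if (!length(A) || !length(B)) stop("both loci must contain proteins")
  idsA <- vapply(A, `[[`, "", "id"); idsB <- vapply(B, `[[`, "", "id")
  if (anyDuplicated(idsA) || anyDuplicated(idsB))
    stop("protein ids within a locus must be unique")

  aln <- vector("list", length(A) * length(B))
  dim(aln) <- c(length(A), length(B))
  scores <- matrix(-Inf, length(A), length(B))
  for (i in seq_along(A)) for (j in seq_along(B)) {
    aln[[i, j]] <- local_align(A[[i]], B[[j]], matrix = matrix,
                               gap_open = gap_open, gap_extend = gap_extend)
    scores[i, j] <- aln[[i, j]]$score
  }
  best_of <- function(v, ids) order(-v, ids)[1L]  # highest score, then id
  bestB <- vapply(seq_along(A), function(i) best_of(scores[i, ], idsB), 1L)
  bestA <- vapply(seq_along(B), function(j) best_of(scores[, j], idsA), 1L)

  rows <- list()
  for (i in seq_along(A)) {
    j <- bestB[i]
    if (bestA[j] == i) {
      call <- is_ortholog(aln[[i, j]], ...)
      al <- aln[[i, j]]
      rows[[length(rows) + 1L]] <- data.frame(
        query = idsA[i], subject = idsB[j], score = al$score,
        identity_pct = al$identity_pct,
        query_coverage = al$query_coverage,
        subject_coverage = al$subject_coverage,
        is_ortholog = call$is_ortholog)
    }
  }
  if (!length(rows))
    return(data.frame(query = character(), subject = character(),
                      score = numeric(), identity_pct = numeric(),
                      query_coverage = numeric(), subject_coverage = numeric(),
                      is_ortholog = logical()))
  do.call(rbind, rows)
}

#' Average amino acid identity over orthologous pairs
#'
#' Arithmetic mean of the percent identity over the pairs called orthologous.
#' With no orthologs the mean is undefined and flagged `NA`.
#'
#' @param calls a data.frame from [reciprocal_best_pairs()], or a list of
#'   [is_ortholog()] calls.
#' @return An object of class `locus_summary`: `n_pairs` (orthologous pairs),
#'   `average_identity_pct`, and the per-pair table.
#' @export
average_aai <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- do.call(rbind, lapply(calls, function(cl) {
      stopifnot(inherits(cl, "orthology_call"))
      data.frame(query = cl$query, subject = cl$subject,
                 score = cl$alignment$score,
                 identity_pct = cl$alignment$identity_pct,
                 query_coverage = cl$alignment$query_coverage,
                 subject_coverage = cl$alignment$subject_coverage,
                 is_ortholog = cl$is_ortholog)
    }))
    if (is.null(calls)) calls <- data.frame(identity_pct = numeric(),
                                            is_ortholog = logical())
  }
  orth <- calls[calls$is_ortholog, , drop = FALSE]
  structure(list(
    n_pairs = nrow(orth),
    average_identity_pct = if (nrow(orth)) mean(orth$identity_pct) else NA_real_,
    calls = calls),
    class = "locus_summary")
}

#' @export
print.locus_summary <- function(x, ...) {
  if (x$n_pairs == 0)
    cat("Locus comparison: no orthologous pairs (AAI undefined)\n")
  else
    cat(sprintf("Locus comparison: %d orthologous pair(s), AAI %.2f%%\n",
                x$n_pairs, x$average_identity_pct))
  invisible(x)
}

#' Locus-versus-locus average amino acid identity
#'
#' Convenience wrapper: [reciprocal_best_pairs()] followed by
#' [average_aai()].
#'
#' @inheritParams reciprocal_best_pairs
#' @param ... thresholds passed to [is_ortholog()].
#' @return A `locus_summary`, see [average_aai()].
#' @export
locus_aai <- function(locusA, locusB, ...) {
  average_aai(reciprocal_best_pairs(locusA, locusB, ...))
}

#' G+C content of a nucleotide sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` bases are excluded from the
#' denominator.
#'
#' @param seq nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @return Percentage in `[0, 100]`.
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(seq) {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("empty nucleotide sequence")
  chars <- factor(strsplit(seq, "")[[1]], levels = c("A", "C", "G", "T", "N"))
  if (anyNA(chars)) stop("invalid nucleotide letters (alphabet is A/C/G/T/N)")
  counts <- table(chars)
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0) stop("sequence contains only N bases")
  100 * sum(counts[c("G", "C")]) / denom
}

#' Locus G+C deviation from the genome average
#'
#' Signed difference, in percentage points, between a locus's G+C content and
#' the host genome's average G+C -- a screening signal for horizontally
#' acquired loci.
#'
#' @param locus_seq locus nucleotide sequence (string), or a pre-computed
#'   locus G+C percentage.
#' @param genome_gc_pct genome-average G+C percentage.
#' @return An object of class `gc_result`: `locus_gc_pct`, `genome_gc_pct`,
#'   `deviation_pp`.
#' @examples
#' gc_deviation(48.45, genome_gc_pct = 43.9)  # +4.55 pp
#' @export
gc_deviation <- function(locus_seq, genome_gc_pct) {
  if (!is.numeric(genome_gc_pct) || genome_gc_pct < 0 || genome_gc_pct > 100)
    stop("genome_gc_pct must be in [0, 100]")
  locus_gc <- if (is.numeric(locus_seq)) {
    if (locus_seq < 0 || locus_seq > 100) stop("locus G+C must be in [0, 100]")
    locus_seq
  } else gc_content(locus_seq)
  structure(list(locus_gc_pct = locus_gc, genome_gc_pct = genome_gc_pct,
                 deviation_pp = locus_gc - genome_gc_pct),
            class = "gc_result")
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("locus G+C %.2f%% vs genome %.2f%%: deviation %+.2f pp\n",
              x$locus_gc_pct, x$genome_gc_pct, x$deviation_pp))
  invisible(x)
}

#' Mutate a protein to a target percent identity
#'
#' Fixture generator: substitutes uniformly chosen positions with uniformly
#' chosen different residues, adjusting the substitution count until the
#' realized identity of the mutant against the original (by [local_align()])
#' is within 2 percentage points of the target. Seeded and reproducible.
#'
#' @param seq a [protein_record()] or string.
#' @param target_identity_pct desired identity in `(0, 100]`.
#' @param seed integer seed.
#' @param max_iter attempts before giving up (short sequences may make a
#'   target unreachable).
#' @return A `protein_record` whose id gains a `_mut` suffix.
#' @export
mutate_protein <- function(seq, target_identity_pct, seed = 1L,
                           max_iter = 60L) {
  p <- as_protein(seq)
  if (target_identity_pct <= 0 || target_identity_pct > 100)
    stop("target identity must be in (0, 100]")
  if (target_identity_pct == 100)
    return(protein_record(paste0(p$id, "_mut"), p$sequence))

  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  chars <- strsplit(p$sequence, "")[[1]]
  L <- length(chars)
  k <- max(1L, round(L * (1 - target_identity_pct / 100)))
  for (iter in seq_len(max_iter)) {
    k <- max(1L, min(L, k))
    mut <- chars
    pos <- sample.int(L, k)
    for (i in pos) mut[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1L)
    cand <- protein_record(paste0(p$id, "_mut"), paste(mut, collapse = ""))
    realized <- local_align(cand, p)$identity_pct
    if (abs(realized - target_identity_pct) <= 2) return(cand)
    # more substitutions if still too similar, fewer if overshot
    k <- k + if (realized > target_identity_pct) max(1L, ceiling(L * 0.02))
             else -max(1L, ceiling(L * 0.02))
    if (k > L && realized > target_identity_pct + 2)
      stop("target identity unreachable for this sequence length")
  }
  stop("target identity not reached within max_iter (sequence too short?)")
}
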