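# Sequence preprocessing: FASTA input, template assignment, homolog
# filtering, database-collection filters, clustering, dimer alignment.

AA_ALPHABET20X <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                    "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

# normalize a sequence collection to a validated named character vector
as_sequence_set <- function(seqs, what = "sequence set") {
  if (methods::is(seqs, "XStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  if (!is.character(seqs) || length(seqs) == 0) {
    abort(what, " must be a nonempty named character vector or AAStringSet")
  }
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    abort(what, " has records with empty ids")
  }
  # ids are the first whitespace-delimited header token
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    abort(what, " has duplicate ids: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(gsub("\\s", "", seqs))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(what, " has empty sequences for: ",
          paste(ids[empty], collapse = ", "))
  }
  bad <- vapply(strsplit(seqs, ""), function(ch) {
    !all(ch %in% AA_ALPHABET20X)
  }, logical(1))
  if (any(bad)) {
    abort(what, " has non-amino-acid letters in: ",
          paste(ids[bad], collapse = ", "))
  }
  setNames(seqs, ids)
}

#' Read candidate protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of uppercase sequences, one element per
#'   record, in file order. An empty file yields an empty vector.
#' @details Record ids (the first whitespace-delimited header token) must be
#'   nonempty and unique; sequences must be nonempty and drawn from the 20
#'   standard one-letter codes plus X. Violations raise an error naming the
#'   offending record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort("malformed FASTA in ", path, ": ",
                              conditionMessage(e))
  )
  if (length(set) == 0) return(setNames(character(0), character(0)))
  as_sequence_set(set, what = path)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_sequence_set(seqs)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

align_pair <- function(a, b, gap_opening = 10, gap_extension = 0.5,
                       substitution_matrix = "BLOSUM62") {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  list(
    query_row = as.character(Biostrings::alignedPattern(al)),
    template_row = as.character(Biostrings::alignedSubject(al))
  )
}

identity_from_rows <- function(qrow, trow, denominator) {
  qc <- strsplit(qrow, "")[[1]]
  tc <- strsplit(trow, "")[[1]]
  matches <- sum(qc == tc & qc != "-")
  denom <- switch(denominator,
    alignment_columns = length(qc),
    shorter_sequence = min(sum(qc != "-"), sum(tc != "-")),
    abort("unknown identity denominator: ", denominator)
  )
  matches / denom
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, gap
#' extension 0.5) followed by an identity computation with a selectable
#' denominator: `alignment_columns` (identical columns over all alignment
#' columns, the template-assignment convention) or `shorter_sequence`
#' (identical columns over the shorter input length, the clustering-tool
#' convention).
#'
#' @param a,b Amino-acid sequences (plain strings or length-1 named vectors).
#' @param denominator Identity denominator convention.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @param substitution_matrix Substitution matrix name.
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b,
                              denominator = c("alignment_columns",
                                              "shorter_sequence"),
                              gap_opening = 10, gap_extension = 0.5,
                              substitution_matrix = "BLOSUM62") {
  denominator <- match.arg(denominator)
  a <- unname(a); b <- unname(b)
  if (!nzchar(a) || !nzchar(b)) abort("cannot align an empty sequence")
  rows <- align_pair(a, b, gap_opening, gap_extension, substitution_matrix)
  identity_from_rows(rows$query_row, rows$template_row, denominator)
}

#' Align a query to a template and keep the gapped rows
#'
#' @inheritParams pairwise_identity
#' @return A `pairwise_alignment` list with `query_row`, `template_row`
#'   (equal-length gapped strings) and `identity` (alignment-column
#'   denominator).
#' @export
align_sequences <- function(a, b, gap_opening = 10, gap_extension = 0.5,
                            substitution_matrix = "BLOSUM62") {
  a <- unname(a); b <- unname(b)
  if (!nzchar(a) || !nzchar(b)) abort("cannot align an empty sequence")
  rows <- align_pair(a, b, gap_opening, gap_extension, substitution_matrix)
  structure(
    list(query_row = rows$query_row, template_row = rows$template_row,
         identity = identity_from_rows(rows$query_row, rows$template_row,
                                       "alignment_columns")),
    class = "pairwise_alignment"
  )
}

#' Assign the closest characterized template to a query sequence
#'
#' Computes the global-alignment identity between the query and every
#' template and returns the template with the highest identity; ties break
#' to the lexicographically smallest template id.
#'
#' @param query Length-1 named character vector (the query sequence).
#' @param templates Named character vector of template sequences keyed by
#'   template id (e.g. PDB code).
#' @param ... Passed to [pairwise_identity()].
#' @return A `template_hit` list with `query_id`, `template_id`, `identity`.
#' @export
assign_template <- function(query, templates, ...) {
  templates <- as_sequence_set(templates, "template library")
  query_id <- if (!is.null(names(query))) names(query)[1] else "query"
  if (!nzchar(unname(query)[1])) abort("query sequence is empty")
  idents <- vapply(templates, function(t) {
    pairwise_identity(query, t, denominator = "alignment_columns", ...)
  }, numeric(1))
  ord <- order(-idents, names(templates))
  best <- ord[1]
  structure(
    list(query_id = query_id, template_id = names(templates)[best],
         identity = unname(idents[best])),
    class = "template_hit"
  )
}

#' Retain queries whose closest template is a characterized IRED
#'
#' @param queries Named character vector of candidate sequences.
#' @param templates Named character vector of template sequences.
#' @param ired_ids Template ids accepted as characterized IREDs.
#' @param ... Passed to [assign_template()].
#' @return The subset of `queries` (order preserved) whose assigned template
#'   id is in `ired_ids`.
#' @export
filter_putative_ireds <- function(queries, templates,
                                  ired_ids = IRED_TEMPLATE_IDS, ...) {
  if (length(queries) == 0) return(queries)
  queries <- as_sequence_set(queries, "query set")
  keep <- vapply(seq_along(queries), function(i) {
    hit <- assign_template(queries[i], templates, ...)
    hit$template_id %in% ired_ids
  }, logical(1))
  queries[keep]
}

#' Filter homology-search hit records
#'
#' Keeps hits with identity strictly above `min_identity`, coverage strictly
#' above `min_coverage` and E-value strictly below `max_e_value`.
#'
#' @param hits Data frame with columns `query_id`, `subject_id`, `identity`,
#'   `coverage`, `e_value` (fractions for identity/coverage).
#' @param cfg A [homology_filter_config()].
#' @return The retained rows of `hits`.
#' @export
apply_homology_filters <- function(hits, cfg = homology_filter_config()) {
  need <- c("query_id", "subject_id", "identity", "coverage", "e_value")
  if (!is.data.frame(hits) || !all(need %in% names(hits))) {
    abort("`hits` must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(hits) == 0) return(hits)
  if (any(hits$identity < 0 | hits$identity > 1) ||
      any(hits$coverage < 0 | hits$coverage > 1)) {
    abort("identity and coverage must be fractions in [0, 1]")
  }
  if (any(hits$e_value < 0)) abort("E-values must be nonnegative")
  keep <- hits$identity > cfg$min_identity &
    hits$coverage > cfg$min_coverage &
    hits$e_value < cfg$max_e_value
  hits[keep, , drop = FALSE]
}

#' Read homology hits from CSV
#'
#' @param path CSV with header `query_id,subject_id,identity,coverage,e_value`.
#' @return Data frame of hit records.
#' @export
read_homology_hits <- function(path) {
  hits <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("query_id", "subject_id", "identity", "coverage", "e_value")
  if (!all(need %in% names(hits))) {
    abort(path, " must have columns ", paste(need, collapse = ", "))
  }
  hits
}

#' Remove duplicates and cluster sequences by identity
#'
#' Exact duplicate sequences are removed (first occurrence kept), then the
#' remainder are clustered greedily longest-first: each sequence joins the
#' first existing cluster whose representative has pairwise identity at
#' least `threshold` (shorter-sequence denominator), otherwise it founds a
#' new cluster. Mirrors the representative-picking behavior of standard
#' identity-clustering tools, without their word-filter heuristics.
#'
#' @param seqs Named character vector of sequences.
#' @param threshold Identity threshold in (0, 1].
#' @param ... Passed to [pairwise_identity()].
#' @return Named character vector of cluster representatives in founding
#'   order.
#' @export
dedupe_and_cluster <- function(seqs, threshold = 0.7, ...) {
  assert_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1]")
  if (length(seqs) == 0) return(seqs)
  seqs <- as_sequence_set(seqs)
  seqs <- seqs[!duplicated(unname(seqs))]
  ord <- order(-nchar(seqs))
  reps <- character(0)
  for (i in ord) {
    joined <- FALSE
    for (r in reps) {
      if (pairwise_identity(seqs[i], seqs[r],
                            denominator = "shorter_sequence",
                            ...) >= threshold) {
        joined <- TRUE
        break
      }
    }
    if (!joined) reps <- c(reps, names(seqs)[i])
  }
  seqs[reps]
}

#' Double a single-chain alignment into a homodimer alignment
#'
#' IREDs are homodimers with the active site at the monomer interface, so
#' the modeling backend needs both chains in the alignment. Each aligned row
#' becomes `row + chain_break + row`; the gap pattern is identical in both
#' copies by construction.
#'
#' @param aln A `pairwise_alignment` from [align_sequences()].
#' @param chain_break Chain-separator token (default `"/"`).
#' @return A `pairwise_alignment` with doubled rows.
#' @export
build_dimer_alignment <- function(aln, chain_break = "/") {
  if (!inherits(aln, "pairwise_alignment")) {
    abort("`aln` must be a pairwise_alignment")
  }
  if (!nzchar(aln$query_row) || !nzchar(aln$template_row)) {
    abort("cannot double an empty alignment")
  }
  if (nchar(aln$query_row) != nchar(aln$template_row)) {
    abort("alignment rows differ in length")
  }
  structure(
    list(
      query_row = paste0(aln$query_row, chain_break, aln$query_row),
      template_row = paste0(aln$template_row, chain_break,
                            aln$template_row),
      identity = aln$identity,
      chain_break = chain_break
    ),
    class = "pairwise_alignment"
  )
}

#' Write an alignment in PIR-style text
#'
#' @param aln A `pairwise_alignment` (single- or double-chain).
#' @param query_id,template_id Record names for the two rows.
#' @param path Output path.
#' @export
write_pir <- function(aln, query_id, template_id, path) {
  if (!inherits(aln, "pairwise_alignment")) {
    abort("`aln` must be a pairwise_alignment")
  }
  lines <- c(
    paste0(">P1;", query_id),
    paste0("sequence:", query_id, ":::::::0.00: 0.00"),
    paste0(aln$query_row, "*"),
    "",
    paste0(">P1;", template_id),
    paste0("structureX:", template_id, ":::::::0.00: 0.00"),
    paste0(aln$template_row, "*")
  )
  writeLines(lines, path)
  invisible(path)
}
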