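# Alignment handling: reading, filtering, reweighting, site statistics and
# candidate substitution sets for the design step.

new_alignment <- function(seqs, ids, focus_columns, target_index,
                          target_offset = 1L,
                          alphabet = gapped_alphabet(),
                          target_positions = NULL,
                          weights = NULL, meff = NULL) {
  stopifnot(is.matrix(seqs), length(ids) == nrow(seqs))
  if (is.null(target_positions)) {
    target_positions <- seq_along(focus_columns) + target_offset - 1L
  }
  structure(list(
    seqs = seqs, ids = ids,
    focus_columns = as.integer(focus_columns),
    target_index = as.integer(target_index),
    target_offset = as.integer(target_offset),
    target_positions = as.integer(target_positions),
    alphabet = alphabet,
    weights = weights, meff = meff
  ), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: %d sequences, %d focus columns (offset %d)\n",
              nrow(x$seqs), length(x$focus_columns), x$target_offset))
  if (!is.null(x$meff)) cat(sprintf("  Meff = %.2f\n", x$meff))
  invisible(x)
}

#' Number of modeled (focus) positions of an alignment
#' @param aln An alignment as returned by [read_alignment()].
#' @return Integer number of focus columns.
#' @export
alignment_length <- function(aln) length(aln$focus_columns)

# Matrix of residues restricted to the focus columns.
focus_matrix <- function(aln) {
  aln$seqs[, aln$focus_columns, drop = FALSE]
}

parse_stockholm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                   nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  ids <- vapply(parts, `[[`, "", 1L)
  seqs <- vapply(parts, function(p) paste(p[-1], collapse = ""), "")
  # multi-block files repeat identifiers; concatenate in block order
  split_seqs <- vapply(unique(ids), function(id)
    paste(seqs[ids == id], collapse = ""), "")
  list(ids = unique(ids), seqs = unname(split_seqs))
}

#' Read a protein family alignment
#'
#' Reads a multiple sequence alignment and anchors it on a target record:
#' the focus columns are those where the target carries a residue, so that
#' focus position `i` corresponds to protein residue `i + offset - 1`.
#' A2M input drops per-sequence insert states (lowercase and `.`) before
#' anchoring, so only match columns remain; Stockholm files are converted on
#' read.
#'
#' @param path Path to the alignment file.
#' @param format One of `"fasta"`, `"a2m"`, `"stockholm"`.
#' @param target_id Identifier of the target (wild-type) record; matched
#'   against the full header and against the token before the first space.
#' @param offset Protein numbering of the first focus position (e.g. 2188
#'   for the Factor VIII C2 domain).
#' @return An `alignment` object.
#' @export
read_alignment <- function(path, format = c("fasta", "a2m", "stockholm"),
                           target_id, offset = 1L) {
  format <- match.arg(format)
  if (format %in% c("fasta", "a2m")) {
    ss <- Biostrings::readBStringSet(path)
    ids <- names(ss)
    seqs <- as.character(ss)
  } else {
    st <- parse_stockholm(path)
    ids <- st$ids
    seqs <- st$seqs
  }
  if (format == "a2m") {
    # insert states are unaligned; removing them leaves the match alignment
    seqs <- gsub("[a-z.]", "", seqs)
  }
  nch <- nchar(seqs)
  if (length(unique(nch)) != 1L) {
    stop("inconsistent aligned sequence lengths: ",
         paste(unique(nch), collapse = ", "))
  }
  short_ids <- sub("\\s.*$", "", ids)
  ti <- which(ids == target_id | short_ids == target_id)
  if (length(ti) == 0L) stop("target record '", target_id, "' not found")
  ti <- ti[1L]
  mat <- matrix(toupper(unlist(strsplit(seqs, ""), use.names = FALSE)),
                nrow = length(seqs), byrow = TRUE)
  mat[mat == "."] <- "-"
  # non-standard residue codes (X, B, Z, ...) carry no usable signal
  mat[!(mat %in% gapped_alphabet())] <- "-"
  focus <- which(mat[ti, ] != "-")
  if (length(focus) == 0L) stop("target record is all gaps")
  new_alignment(mat, short_ids, focus, ti, as.integer(offset))
}

#' Filter gappy sequences and columns
#'
#' Removes sequences whose gap fraction over the focus columns is at least
#' `max_row_gap` and focus columns whose gap fraction exceeds `max_col_gap`,
#' iterating the two rules to a fixed point so that the result is idempotent
#' and both postconditions hold simultaneously.
#'
#' @param aln An `alignment`.
#' @param max_row_gap Sequences with gap fraction `>=` this are dropped;
#'   the target record is always retained.
#' @param max_col_gap Columns with gap fraction `>` this are dropped.
#' @return The filtered `alignment`; previously computed weights are
#'   invalidated.
#' @export
filter_alignment <- function(aln, max_row_gap = 0.7, max_col_gap = 0.5) {
  stopifnot(max_row_gap > 0, max_row_gap <= 1,
            max_col_gap > 0, max_col_gap <= 1)
  keep_rows <- seq_len(nrow(aln$seqs))
  focus <- aln$focus_columns
  positions <- aln$target_positions
  repeat {
    sub <- aln$seqs[keep_rows, focus, drop = FALSE]
    gap <- sub == "-"
    row_frac <- rowMeans(gap)
    drop_rows <- row_frac >= max_row_gap & keep_rows != aln$target_index
    changed <- FALSE
    if (any(drop_rows)) {
      keep_rows <- keep_rows[!drop_rows]
      changed <- TRUE
      gap <- gap[!drop_rows, , drop = FALSE]
    }
    if (length(keep_rows) == 0L) stop("all sequences removed by filtering")
    col_frac <- colMeans(gap)
    if (any(col_frac > max_col_gap)) {
      keep_cols <- col_frac <= max_col_gap
      focus <- focus[keep_cols]
      positions <- positions[keep_cols]
      changed <- TRUE
    }
    if (length(focus) == 0L) stop("all columns removed by filtering")
    if (!changed) break
  }
  new_alignment(aln$seqs[keep_rows, , drop = FALSE], aln$ids[keep_rows],
                focus, match(aln$target_index, keep_rows),
                aln$target_offset, aln$alphabet,
                target_positions = positions)
}

#' Sequence reweighting by identity clustering
#'
#' Assigns each sequence the inverse of the number of alignment members
#' (itself included) whose identity to it, computed over the focus columns
#' with gaps counting as mismatches, reaches `theta`. The sum of weights is
#' the effective sequence number Meff.
#'
#' @param aln An `alignment` (filtered).
#' @param theta Identity threshold in (0, 1]; default 0.9.
#' @return The alignment with `weights` and `meff` filled.
#' @export
sequence_weights <- function(aln, theta = 0.9) {
  stopifnot(theta > 0, theta <= 1)
  if (nrow(aln$seqs) == 0L) stop("empty alignment")
  enc <- encode_seq(focus_matrix(aln), aln$alphabet)
  gap_state <- match("-", aln$alphabet)
  if (is.na(gap_state)) gap_state <- -1L
  counts <- cluster_sizes_cpp(enc, theta, gap_state)
  aln$weights <- 1 / counts
  aln$meff <- sum(aln$weights)
  aln
}

#' Weighted per-position residue frequencies
#'
#' @param aln An `alignment` with weights computed (see
#'   [sequence_weights()]).
#' @return Object of class `site_frequencies`: matrix `f` (position x
#'   alphabet symbol, rows summing to one; the gap is its own symbol when
#'   present), plus the target numbering.
#' @export
site_frequencies <- function(aln) {
  if (is.null(aln$weights)) stop("weights not computed; run sequence_weights()")
  enc <- encode_seq(focus_matrix(aln), aln$alphabet)
  L <- ncol(enc)
  q <- length(aln$alphabet)
  w <- aln$weights
  f <- matrix(0, L, q, dimnames = list(NULL, aln$alphabet))
  for (a in seq_len(q)) {
    f[, a] <- colSums(w * (enc == a))
  }
  f <- f / rowSums(f)
  structure(list(f = f, alphabet = aln$alphabet,
                 target_positions = aln$target_positions),
            class = "site_frequencies")
}

#' Candidate substitution sets from conservation
#'
#' At each mutable position the allowed residues are those whose
#' gap-renormalized frequency reaches `zeta`, with the wild-type residue
#' always included; positions outside `mutable_positions` are pinned to the
#' wild type. Gaps are never allowed in a design.
#'
#' @param freqs A `site_frequencies` object.
#' @param wild_type Wild-type sequence (string or character vector) over the
#'   focus positions.
#' @param zeta Frequency threshold in \[0, 1\].
#' @param mutable_positions Focus-position indices (1..L) allowed to mutate;
#'   default all.
#' @return Object of class `mutation_sets`: list `M` of allowed residue
#'   vectors, the wild type, `zeta` and the mutable positions.
#' @export
mutation_sets <- function(freqs, wild_type, zeta,
                          mutable_positions = NULL) {
  stopifnot(zeta >= 0, zeta <= 1)
  f <- freqs$f
  L <- nrow(f)
  wt <- if (length(wild_type) == 1L) seq_chars(wild_type) else wild_type
  stopifnot(length(wt) == L)
  if (is.null(mutable_positions)) mutable_positions <- seq_len(L)
  aas <- setdiff(colnames(f), "-")
  fa <- f[, aas, drop = FALSE]
  rs <- rowSums(fa)
  rs[rs == 0] <- 1       # all-gap column: only the wild type survives
  fa <- fa / rs
  M <- vector("list", L)
  for (i in seq_len(L)) {
    if (i %in% mutable_positions) {
      allowed <- aas[fa[i, ] >= zeta]
      M[[i]] <- union(wt[i], allowed)
      # keep alphabet ordering, wild type first for readability
      M[[i]] <- c(wt[i], setdiff(aas[aas %in% M[[i]]], wt[i]))
    } else {
      M[[i]] <- wt[i]
    }
  }
  structure(list(M = M, wild_type = wt, zeta = zeta,
                 mutable_positions = as.integer(mutable_positions),
                 target_positions = freqs$target_positions),
            class = "mutation_sets")
}

#' Write an alignment to FASTA
#' @param aln An `alignment`.
#' @param path Output path.
#' @param focus_only Write only the focus columns (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_alignment_fasta <- function(aln, path, focus_only = TRUE) {
  mat <- if (focus_only) focus_matrix(aln) else aln$seqs
  seqs <- apply(mat, 1L, paste, collapse = "")
  writeLines(paste0(">", aln$ids, "\n", seqs), path)
  invisible(path)
}
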