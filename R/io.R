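#' Read protein sequences from FASTA
#'
#' Reads amino-acid FASTA into a tibble of protein records. The header token
#' before the first whitespace becomes the id, sequences are uppercased, and
#' ambiguous or non-standard letters (B, Z, J, U, O) are mapped to `X`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id: ", dup[1L], call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[BZJUO]", "X", seqs)
  bad <- grepl(paste0("[^", paste(AA_LETTERS, collapse = ""), "X]"), seqs)
  if (any(bad)) {
    stop("sequence for ", ids[which(bad)[1L]],
         " contains non-amino-acid characters", call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for ", ids[which(nchar(seqs) == 0L)[1L]],
         call. = FALSE)
  }
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write protein sequences to FASTA
#'
#' @param proteins Tibble with columns `id` and `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  ss <- Biostrings::BStringSet(proteins$sequence)
  names(ss) <- proteins$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
STY <- c("S", "T", "Y")

residue_at <- function(sequence, position) {
  substr(sequence, position, position)
}

lookup_sequences <- function(proteins, ids) {
  idx <- match(ids, proteins$id)
  if (anyNA(idx)) {
    stop("unknown protein id: ", ids[which(is.na(idx))[1L]], call. = FALSE)
  }
  proteins$sequence[idx]
}

#' Validate candidate phosphosite records against their sequences
#'
#' Checks that every record's residue is S, T or Y, lies within the
#' sequence, and matches the sequence character at its 1-based position.
#'
#' @param sites Tibble with columns `protein_id`, `position` (1-based),
#'   `residue` and `label` (0/1).
#' @param proteins Tibble with columns `id` and `sequence`.
#' @return `sites`, invisibly coerced to canonical column types.
#' @export
validate_sites <- function(sites, proteins) {
  stopifnot(all(c("protein_id", "position", "residue", "label") %in% names(sites)))
  sites <- tibble::as_tibble(sites)
  sites$position <- as.integer(sites$position)
  sites$label <- as.integer(sites$label)
  if (!all(sites$label %in% 0:1)) stop("site labels must be 0/1", call. = FALSE)
  seqs <- lookup_sequences(proteins, sites$protein_id)
  bad <- which(!sites$residue %in% STY)
  if (length(bad) > 0L) {
    stop(sprintf("residue '%s' at %s:%d is not S/T/Y",
                 sites$residue[bad[1L]], sites$protein_id[bad[1L]],
                 sites$position[bad[1L]]), call. = FALSE)
  }
  bad <- which(sites$position < 1L | sites$position > nchar(seqs))
  if (length(bad) > 0L) {
    stop(sprintf("position %d out of bounds for %s (length %d)",
                 sites$position[bad[1L]], sites$protein_id[bad[1L]],
                 nchar(seqs)[bad[1L]]), call. = FALSE)
  }
  actual <- substr(seqs, sites$position, sites$position)
  bad <- which(actual != sites$residue)
  if (length(bad) > 0L) {
    stop(sprintf(
      "residue mismatch at %s:%d: file says '%s' but sequence has '%s'",
      sites$protein_id[bad[1L]], sites$position[bad[1L]],
      sites$residue[bad[1L]], actual[bad[1L]]), call. = FALSE)
  }
  sites
}

#' Read a phosphosite table
#'
#' Reads a tab-separated site table (header row; columns `protein_id`,
#' `position`, `residue`, `label`; `#` comment lines ignored) and validates
#' every record against its protein sequence.
#'
#' @param path Path to the TSV file.
#' @param proteins Tibble of protein records ([read_fasta()]).
#' @return A validated tibble of site records, in file order.
#' @export
read_site_table <- function(path, proteins) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           protein_id = readr::col_character(),
                           position = readr::col_integer(),
                           residue = readr::col_character(),
                           label = readr::col_integer()))
  validate_sites(tab, proteins)
}

#' @rdname read_site_table
#' @param sites Tibble of site records.
#' @export
write_site_table <- function(sites, path) {
  readr::write_tsv(sites[, c("protein_id", "position", "residue", "label")], path)
  invisible(path)
}

#' Validate interaction-effect records
#'
#' Each record names a protein pair, a 1-based site position on protein A
#' (which must index an S/T/Y residue) and a binary effect label
#' (1 = enhancement, 0 = inhibition).
#'
#' @param pairs Tibble with columns `protein_a_id`, `protein_b_id`,
#'   `position` and `label`.
#' @param proteins Tibble of protein records.
#' @return `pairs` with canonical column types.
#' @export
validate_pairs <- function(pairs, proteins) {
  stopifnot(all(c("protein_a_id", "protein_b_id", "position", "label") %in%
                  names(pairs)))
  pairs <- tibble::as_tibble(pairs)
  pairs$position <- as.integer(pairs$position)
  pairs$label <- as.integer(pairs$label)
  if (!all(pairs$label %in% 0:1)) stop("effect labels must be 0/1", call. = FALSE)
  seq_a <- lookup_sequences(proteins, pairs$protein_a_id)
  lookup_sequences(proteins, pairs$protein_b_id)  # existence check
  bad <- which(pairs$position < 1L | pairs$position > nchar(seq_a))
  if (length(bad) > 0L) {
    stop(sprintf("position %d out of bounds for %s",
                 pairs$position[bad[1L]], pairs$protein_a_id[bad[1L]]),
         call. = FALSE)
  }
  res <- substr(seq_a, pairs$position, pairs$position)
  bad <- which(!res %in% STY)
  if (length(bad) > 0L) {
    stop(sprintf("site %s:%d is '%s', not S/T/Y",
                 pairs$protein_a_id[bad[1L]], pairs$position[bad[1L]],
                 res[bad[1L]]), call. = FALSE)
  }
  pairs
}

#' Read an interaction-effect table
#'
#' Tab-separated with header; columns `protein_a_id`, `protein_b_id`,
#' `position`, `label`; `#` comment lines ignored.
#'
#' @inheritParams read_site_table
#' @return A validated tibble of effect records, in file order.
#' @export
read_ppi_table <- function(path, proteins) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           protein_a_id = readr::col_character(),
                           protein_b_id = readr::col_character(),
                           position = readr::col_integer(),
                           label = readr::col_integer()))
  validate_pairs(tab, proteins)
}

#' @rdname read_ppi_table
#' @param pairs Tibble of effect records.
#' @export
write_ppi_table <- function(pairs, path) {
  readr::write_tsv(pairs[, c("protein_a_id", "protein_b_id", "position", "label")],
                   path)
  invisible(path)
}

#' Balance negative sites against positives by residue-stratified sampling
#'
#' Keeps all positive records and samples exactly `nrow(positives)`
#' negatives without replacement, stratified by residue type so that the
#' S/T/Y proportions of the negative pool are preserved to the nearest
#' integer (floor plus largest-fractional-part remainder allocation, capped
#' at stratum size). Deterministic given `seed`.
#'
#' @param positives,negatives Tibbles of site records ([read_site_table()]).
#' @param seed Integer RNG seed.
#' @return A tibble of all positives followed by the sampled negatives.
#' @export
balance_negatives <- function(positives, negatives, seed) {
  if (nrow(negatives) < nrow(positives)) {
    stop("cannot balance: fewer negatives (", nrow(negatives),
         ") than positives (", nrow(positives), ")", call. = FALSE)
  }
  m <- nrow(positives)
  counts <- vapply(STY, function(r) sum(negatives$residue == r), integer(1))
  frac <- m * counts / sum(counts)
  alloc <- floor(frac)
  rem <- m - sum(alloc)
  if (rem > 0) {
    spare <- counts - alloc
    ord <- order(frac - alloc, decreasing = TRUE)
    for (i in ord) {
      if (rem == 0) break
      if (spare[i] > 0) {
        alloc[i] <- alloc[i] + 1L
        rem <- rem - 1L
      }
    }
  }
  rng <- rng_local(seed)
  picked <- lapply(seq_along(STY), function(i) {
    pool <- which(negatives$residue == STY[i])
    pool[rng$sample_n(length(pool), alloc[i])]
  })
  dplyr::bind_rows(positives, negatives[sort(unlist(picked)), ])
}

#' Label-stratified train/test split
#'
#' Splits records into train and test with `round(ratio * n)` training
#' records per label stratum (test receives the remainder); deterministic
#' given `seed`.
#'
#' @param records A tibble with a `label` column.
#' @param ratio Training fraction in (0, 1).
#' @param seed Integer RNG seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(records, ratio, seed) {
  stopifnot(nrow(records) >= 2L, ratio > 0, ratio < 1)
  rng <- rng_local(seed)
  train_idx <- integer(0)
  for (lab in sort(unique(records$label))) {
    idx <- which(records$label == lab)
    if (length(idx) < 2L) {
      stop("label stratum ", lab, " has fewer than 2 records", call. = FALSE)
    }
    k <- round(ratio * length(idx))
    train_idx <- c(train_idx, idx[rng$sample_n(length(idx), k)])
  }
  list(train = records[sort(train_idx), ],
       test = records[setdiff(seq_len(nrow(records)), train_idx), ])
}

#' Drop training pairs that overlap a test set
#'
#' Removes every training record whose ordered key
#' `(protein_a_id, protein_b_id, position)` appears in any of the test
#' collections. The key is directional: protein A carries the site, so
#' `(A, B, p)` does not match `(B, A, p)`. Survivor order is preserved.
#'
#' @param train Tibble of effect records.
#' @param tests A tibble of effect records, or a list of such tibbles.
#' @return The filtered training tibble.
#' @export
remove_overlaps <- function(train, tests) {
  if (is.data.frame(tests)) tests <- list(tests)
  key <- function(x) paste(x$protein_a_id, x$protein_b_id, x$position, sep = "\r")
  test_keys <- unlist(lapply(tests, key))
  train[!key(train) %in% test_keys, ]
}
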