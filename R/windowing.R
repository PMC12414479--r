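#' Extract the fixed-length residue window around a candidate site
#'
#' Cuts the `2 * half_width + 1` residue window centered on a 1-based
#' position, padding out-of-range slots with `*`. With the default
#' `half_width = 15` this is the 31-residue window (15 residues upstream,
#' the target, 15 downstream) used by the interaction-effect models.
#'
#' @param protein A one-row tibble (or list) with `id` and `sequence`.
#' @param position 1-based center position.
#' @param half_width Residues on each side of the center (default 15).
#' @param enforce_sty Require the center residue to be S, T or Y
#'   (default `TRUE`).
#' @return A list of class `phosppi_window` with `protein_id`, `position`,
#'   `window_seq` (string of length `2 * half_width + 1`), `mask` (integer
#'   vector; 1 = real residue, 0 = pad) and `half_width`. The embedding
#'   slot `window_emb` is filled by [window_embedding()].
#' @export
extract_window <- function(protein, position, half_width = 15L,
                           enforce_sty = TRUE) {
  seq <- protein$sequence[[1]]
  L <- nchar(seq)
  position <- as.integer(position)
  if (position < 1L || position > L) {
    stop(sprintf("position %d out of bounds for %s (length %d)",
                 position, protein$id[[1]], L), call. = FALSE)
  }
  center <- substr(seq, position, position)
  if (enforce_sty && !center %in% STY) {
    stop(sprintf("residue '%s' at %s:%d is not S/T/Y",
                 center, protein$id[[1]], position), call. = FALSE)
  }
  offs <- seq.int(position - half_width, position + half_width)
  inside <- offs >= 1L & offs <= L
  chars <- rep("*", length(offs))
  chars[inside] <- strsplit(substr(seq, max(position - half_width, 1L),
                                   min(position + half_width, L)), "")[[1]]
  structure(
    list(protein_id = protein$id[[1]], position = position,
         window_seq = paste(chars, collapse = ""),
         mask = as.integer(inside), half_width = as.integer(half_width),
         window_emb = NULL),
    class = "phosppi_window"
  )
}

#' Attach embedding rows to a site window
#'
#' Copies the corresponding rows of the protein's full-sequence embedding
#' into the window (embed first, slice second, so the rows retain the
#' model's long-range context); pad slots receive [pad_vector()].
#'
#' @param window A `phosppi_window` from [extract_window()].
#' @param emb A `phosppi_embedding` of the same protein.
#' @return The window with `window_emb` set to a `(2 * half_width + 1) x D`
#'   matrix.
#' @export
window_embedding <- function(window, emb) {
  stopifnot(inherits(window, "phosppi_window"),
            inherits(emb, "phosppi_embedding"))
  if (!identical(window$protein_id, emb$protein_id)) {
    stop("window and embedding belong to different proteins", call. = FALSE)
  }
  w <- window$half_width
  offs <- seq.int(window$position - w, window$position + w)
  real <- which(window$mask == 1L)
  if (max(offs[real]) > nrow(emb$values)) {
    stop(sprintf(
      "site %s:%d lies beyond the (truncated) embedding of %d rows",
      window$protein_id, window$position, nrow(emb$values)), call. = FALSE)
  }
  m <- matrix(0, length(offs), emb$dim)
  m[real, ] <- emb$values[offs[real], , drop = FALSE]
  window$window_emb <- m
  window
}

#' @export
print.phosppi_window <- function(x, ...) {
  cat(sprintf("<phosppi_window> %s:%d  %s  (%d real residues)\n",
              x$protein_id, x$position, x$window_seq, sum(x$mask)))
  invisible(x)
}

#' Export site windows as a tibble
#'
#' @param sites Tibble of site records.
#' @param proteins Tibble of protein records.
#' @param half_width Residues on each side of the center.
#' @return A tibble with `protein_id`, `position` and `window_seq`,
#'   suitable for [readr::write_tsv()].
#' @export
window_table <- function(sites, proteins, half_width = 15L) {
  seqs <- lookup_sequences(proteins, sites$protein_id)
  ws <- vapply(seq_len(nrow(sites)), function(i) {
    extract_window(list(id = sites$protein_id[i], sequence = seqs[i]),
                   sites$position[i], half_width,
                   enforce_sty = FALSE)$window_seq
  }, character(1))
  tibble::tibble(protein_id = sites$protein_id, position = sites$position,
                 window_seq = ws)
}
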