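#' Embedding backends
#'
#' An embedding backend turns a protein sequence into an L x D matrix of
#' per-residue embeddings. `mock_backend()` is a deterministic,
#' download-free stand-in for a protein language model: each residue's row
#' is a hashed function of its trigram context (the residue and its two
#' neighbours), so the representation is context-sensitive like a PLM while
#' requiring no weights. `plm_backend()` declares a real protein language
#' model backend (ProtBERT, D = 1024, or ESM-2, D = 1280) through a
#' user-supplied embedding function; without one, embedding through it
#' raises a "backend unavailable" error rather than silently falling back.
#'
#' @param dim Embedding dimension (mock backend; >= 4).
#' @param seed Integer seed for the mock hash.
#' @param max_length Maximum sequence length; longer sequences are
#'   truncated to their N-terminal prefix with a warning. Mock default is
#'   unlimited; PLM backends default to 1022.
#' @param name For `plm_backend()`: `"protbert"` or `"esm2"`.
#' @param embed_fn Optional function `(sequence) -> L x D matrix` wiring a
#'   real model into the backend.
#' @return An object of class `phosppi_backend`.
#' @export
mock_backend <- function(dim = 32L, seed = 1L, max_length = Inf) {
  stopifnot(dim >= 4L)
  structure(
    list(name = "mock", dim = as.integer(dim), seed = as.integer(seed),
         max_length = max_length, embed_fn = NULL,
         cache = new.env(parent = emptyenv())),
    class = "phosppi_backend"
  )
}

#' @rdname mock_backend
#' @export
plm_backend <- function(name = c("protbert", "esm2"), embed_fn = NULL,
                        max_length = 1022L) {
  name <- match.arg(name)
  dim <- if (name == "protbert") 1024L else 1280L
  structure(
    list(name = name, dim = dim, seed = NA_integer_,
         max_length = max_length, embed_fn = embed_fn,
         cache = new.env(parent = emptyenv())),
    class = "phosppi_backend"
  )
}

#' @export
print.phosppi_backend <- function(x, ...) {
  cat(sprintf("<phosppi_backend> %s (D = %d, max_length = %s)\n",
              x$name, x$dim,
              if (is.finite(x$max_length)) x$max_length else "unlimited"))
  invisible(x)
}

# FNV-1a hash over integer codes, kept in double precision below 2^31
fnv1a <- function(codes) {
  h <- 2166136261
  for (c in codes) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(c))
    h <- (as.double(h) * 16777619) %% 2147483629
  }
  h
}

#' Deterministic mock per-residue embedding
#'
#' Row i encodes the trigram context `(residue i-1, residue i, residue
#' i+1)` (with `^`/`$` boundary markers): each (letter, slot) pair hashes
#' to a fixed Gaussian vector seeded by `seed`, and the row is the sum of
#' the three slot vectors scaled to unit variance. Identical trigrams give
#' identical rows, changing a neighbour changes the row, and — like a real
#' protein language model — the representation is compositional, so a
#' residue contributes a consistent direction across contexts.
#'
#' @param sequence Amino-acid string.
#' @param dim Embedding dimension (>= 4).
#' @param seed Integer seed.
#' @return An `L x dim` numeric matrix.
#' @export
mock_embed <- function(sequence, dim, seed) {
  stopifnot(dim >= 4L, nchar(sequence) >= 1L)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  padded <- c("^", chars, "$")
  slot_vec <- local({
    seen <- new.env(parent = emptyenv())
    function(letter, slot) {
      key <- paste0(letter, slot)
      row <- get0(key, seen, inherits = FALSE)
      if (is.null(row)) {
        h <- fnv1a(c(utf8ToInt(key), as.integer(seed)))
        row <- rng_local(h)$rnorm(dim)
        assign(key, row, seen)
      }
      row
    }
  })
  out <- matrix(0, L, dim)
  for (i in seq_len(L)) {
    out[i, ] <- (slot_vec(padded[i], 1L) + slot_vec(padded[i + 1L], 2L) +
                   slot_vec(padded[i + 2L], 3L)) / sqrt(3)
  }
  out
}

#' The embedding of the pad symbol
#'
#' The `*` pad symbol embeds as the all-zeros vector of length `dim`,
#' shared by every backend, so pads are inert under sum pooling; window
#' masks additionally exclude pad rows from attention and mean pooling.
#'
#' @param dim Embedding dimension.
#' @return A numeric zero vector of length `dim`.
#' @export
pad_vector <- function(dim) {
  stopifnot(dim > 0)
  numeric(dim)
}

#' Embed a protein sequence through a backend
#'
#' Returns the per-residue embedding matrix for one protein, with rows
#' aligned 1:1 with residues. Results are cached in memory per backend and,
#' if `cache_dir` is given, on disk keyed by backend name, dimension and a
#' sequence hash (with the full sequence stored in a JSON index to guard
#' against hash collisions).
#'
#' @param backend A `phosppi_backend`.
#' @param protein A one-row tibble (or list) with `id` and `sequence`.
#' @param cache_dir Optional directory for the on-disk cache.
#' @return A list of class `phosppi_embedding` with `protein_id`, `values`
#'   (L x D matrix) and `dim`.
#' @export
embed_sequence <- function(backend, protein, cache_dir = NULL) {
  stopifnot(inherits(backend, "phosppi_backend"))
  id <- protein$id[[1]]
  seq <- protein$sequence[[1]]
  stopifnot(nchar(seq) >= 1L)
  if (nchar(seq) > backend$max_length) {
    warning(sprintf("sequence %s (length %d) truncated to %d residues",
                    id, nchar(seq), backend$max_length), call. = FALSE)
    seq <- substr(seq, 1L, backend$max_length)
  }
  key <- paste(backend$name, backend$dim, backend$seed, seq, sep = "|")
  hit <- get0(key, backend$cache, inherits = FALSE)
  if (is.null(hit) && !is.null(cache_dir)) hit <- cache_read(cache_dir, backend, seq)
  if (is.null(hit)) {
    hit <- if (backend$name == "mock") {
      mock_embed(seq, backend$dim, backend$seed)
    } else if (!is.null(backend$embed_fn)) {
      m <- backend$embed_fn(seq)
      if (!is.matrix(m) || nrow(m) != nchar(seq) || ncol(m) != backend$dim) {
        stop("embed_fn returned a matrix of the wrong shape", call. = FALSE)
      }
      m
    } else {
      stop("backend unavailable: weights for '", backend$name,
           "' are not installed", call. = FALSE)
    }
    assign(key, hit, backend$cache)
    if (!is.null(cache_dir)) cache_write(cache_dir, backend, seq, hit)
  }
  structure(list(protein_id = id, values = hit, dim = backend$dim),
            class = "phosppi_embedding")
}

cache_paths <- function(cache_dir, backend, seq) {
  h <- fnv1a(c(utf8ToInt(substr(seq, 1, 4096)), nchar(seq)))
  stem <- sprintf("%s_d%d_s%s_%.0f", backend$name, backend$dim, backend$seed, h)
  list(data = file.path(cache_dir, paste0(stem, ".rds")),
       index = file.path(cache_dir, paste0(stem, ".json")))
}

cache_read <- function(cache_dir, backend, seq) {
  p <- cache_paths(cache_dir, backend, seq)
  if (!file.exists(p$data) || !file.exists(p$index)) return(NULL)
  idx <- jsonlite::read_json(p$index)
  if (!identical(idx$sequence, seq)) return(NULL)
  readRDS(p$data)
}

cache_write <- function(cache_dir, backend, seq, values) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cache_paths(cache_dir, backend, seq)
  jsonlite::write_json(list(backend = backend$name, dim = backend$dim,
                            seed = backend$seed, sequence = seq),
                       p$index, auto_unbox = TRUE)
  saveRDS(values, p$data)
  invisible(NULL)
}
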