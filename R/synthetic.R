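#' Synthetic dataset configuration
#'
#' Describes a fully self-contained synthetic study with the structure of
#' the real tasks: candidate sites restricted to S/T/Y residues,
#' class-balanced site labels, and imbalanced (~70/30
#' enhancement/inhibition) pair-level effect labels. A plantable sequence
#' signal makes both tasks learnable: a site is functional when
#' `signal_motif` occupies `motif_offsets` relative to it, and the
#' pair-level label is the XOR of "a functional-site motif lies inside
#' the site's 31-residue window" with the presence of
#' `inhibitor_trigram` in the first 20 residues of partner B — so the
#' effect label provably depends on both proteins.
#'
#' @param n_proteins Number of proteins to generate.
#' @param length_range Integer `(min, max)` sequence lengths; min >= 31.
#' @param n_sites Total site records (balanced by `positive_fraction_sites`).
#' @param n_pairs Total interaction-effect records.
#' @param positive_fraction_sites Fraction of functional site labels
#'   (default 0.5).
#' @param enhancement_fraction Fraction of enhancement pair labels
#'   (default 0.7).
#' @param signal_motif Motif string planted upstream of functional sites
#'   (default `"RR"`).
#' @param motif_offsets Offsets of the motif characters relative to the
#'   site (default `c(-3, -2)`).
#' @param inhibitor_trigram Trigram whose presence in partner B's first 20
#'   residues flips the effect (default `"WWW"`).
#' @param plant_rate Probability that each eligible candidate site gets
#'   the motif planted at its offsets (default 0.2, which also leaves the
#'   presence/absence of the motif within a 31-residue window roughly
#'   balanced across candidate sites).
#' @param noise_rate Probability of flipping each label (default 0).
#' @param plant_signal Plant the motif/trigram signal into sequences?
#'   `FALSE` gives plain i.i.d. sequences (useful for testing the base
#'   sampler).
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_proteins, length_range = c(50L, 80L), n_sites,
                         n_pairs, positive_fraction_sites = 0.5,
                         enhancement_fraction = 0.7, signal_motif = "RR",
                         motif_offsets = c(-3L, -2L),
                         inhibitor_trigram = "WWW", plant_rate = 0.2,
                         noise_rate = 0, plant_signal = TRUE, seed = 1L) {
  stopifnot(length_range[1] >= 31L, length_range[1] <= length_range[2],
            positive_fraction_sites > 0, positive_fraction_sites < 1,
            enhancement_fraction > 0, enhancement_fraction < 1,
            noise_rate >= 0, noise_rate < 1,
            plant_rate > 0, plant_rate < 1,
            nchar(signal_motif) == length(motif_offsets),
            all(diff(motif_offsets) == 1L))
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_sites = as.integer(n_sites), n_pairs = as.integer(n_pairs),
                 positive_fraction_sites = positive_fraction_sites,
                 enhancement_fraction = enhancement_fraction,
                 signal_motif = signal_motif,
                 motif_offsets = as.integer(motif_offsets),
                 inhibitor_trigram = inhibitor_trigram,
                 plant_rate = plant_rate,
                 noise_rate = noise_rate, plant_signal = isTRUE(plant_signal),
                 seed = as.integer(seed)),
            class = "synth_config")
}

count_sty <- function(chars) sum(chars %in% STY)

# does the motif occupy its offsets relative to position p?
motif_at <- function(sequence, p, motif, offsets) {
  start <- p + offsets[1L]
  if (start < 1L || p + offsets[length(offsets)] > nchar(sequence)) return(FALSE)
  substr(sequence, start, start + nchar(motif) - 1L) == motif
}

# is there a functional-site motif near p: a candidate S/T/Y residue q
# inside the half_width window whose offsets carry the motif (motif chars
# inside the window too)?
motif_near <- function(sequence, p, motif, offsets = c(-3L, -2L),
                       half_width = 15L) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  lo <- max(1L - offsets[1L], p - half_width - offsets[1L])
  hi <- min(L, p + half_width)
  if (lo > hi) return(FALSE)
  motif_chars <- strsplit(motif, "")[[1]]
  for (q in lo:hi) {
    if (chars[q] %in% STY && all(chars[q + offsets] == motif_chars)) return(TRUE)
  }
  FALSE
}

has_inhibitor <- function(sequence, trigram) {
  grepl(trigram, substr(sequence, 1L, 20L), fixed = TRUE)
}

#' Generate synthetic proteins
#'
#' Sequences are drawn i.i.d. uniformly over the 20 standard amino acids,
#' resampled until they contain at least 3 S/T/Y residues. With
#' `plant_signal = TRUE` (the default) the upstream motif is written before
#' a `plant_rate` fraction of the eligible candidate sites, scrubbed from
#' the accidental occurrences at the rest,
#' and the inhibitor trigram is planted in (or scrubbed from) the first 20
#' residues of roughly half the proteins.
#'
#' @param cfg A [synth_config()].
#' @return A tibble of protein records (`id`, `sequence`).
#' @export
gen_proteins <- function(cfg) {
  rng <- rng_local(derive_seed(cfg$seed, 1))
  non_motif <- setdiff(AA_LETTERS, strsplit(cfg$signal_motif, "")[[1]])
  non_motif <- setdiff(non_motif, STY)
  out <- character(cfg$n_proteins)
  for (i in seq_len(cfg$n_proteins)) {
    repeat {
      L <- cfg$length_range[1] +
        floor(rng$runif(1) * (cfg$length_range[2] - cfg$length_range[1] + 1L))
      chars <- rng$sample_vec(AA_LETTERS, L, replace = TRUE)
      if (count_sty(chars) < 3L) next
      if (cfg$plant_signal) {
        chars <- plant_protein_signal(chars, cfg, rng, non_motif)
        if (count_sty(chars) < 3L) next
      }
      break
    }
    out[i] <- paste(chars, collapse = "")
  }
  tibble::tibble(id = sprintf("SYN%04d", seq_len(cfg$n_proteins)),
                 sequence = out)
}

plant_protein_signal <- function(chars, cfg, rng, non_motif) {
  L <- length(chars)
  offs <- cfg$motif_offsets
  motif_chars <- strsplit(cfg$signal_motif, "")[[1]]
  eligible <- which(chars %in% STY)
  eligible <- eligible[eligible + offs[1L] >= 1L &
                         eligible + offs[length(offs)] <= L]
  for (p in eligible) {
    slots <- p + offs
    if (rng$rbinom1(cfg$plant_rate)) {
      chars[slots] <- motif_chars
    } else if (all(chars[slots] == motif_chars)) {
      # scrub an accidental motif with a neutral letter
      chars[slots[1L]] <- rng$sample_vec(non_motif, 1L)
    }
  }
  # inhibitor trigram in the first 20 residues of ~half the proteins,
  # planted as a tandem block of three copies so its pooled signature
  # stays visible under sum pooling over the whole sequence
  tri <- strsplit(strrep(cfg$inhibitor_trigram, 3L), "")[[1]]
  k <- length(tri)
  if (rng$rbinom1(0.5)) {
    start <- 1L + floor(rng$runif(1) * (min(20L, L) - k + 1L))
    chars[start:(start + k - 1L)] <- tri
  } else {
    k <- nchar(cfg$inhibitor_trigram)
    head_str <- paste(chars[seq_len(min(20L + k - 1L, L))], collapse = "")
    hit <- regexpr(cfg$inhibitor_trigram, head_str, fixed = TRUE)
    if (hit > 0L && hit <= 20L) {
      chars[hit + (k - 1L) %/% 2L] <- rng$sample_vec(non_motif, 1L)
    }
  }
  chars
}

# all S/T/Y candidate records of a protein set, labeled by the motif rule
candidate_sites <- function(proteins, cfg) {
  recs <- lapply(seq_len(nrow(proteins)), function(i) {
    seq <- proteins$sequence[i]
    chars <- strsplit(seq, "")[[1]]
    pos <- which(chars %in% STY)
    if (length(pos) == 0L) return(NULL)
    lab <- vapply(pos, function(p) {
      motif_at(seq, p, cfg$signal_motif, cfg$motif_offsets)
    }, logical(1))
    tibble::tibble(protein_id = proteins$id[i], position = pos,
                   residue = chars[pos], label = as.integer(lab))
  })
  dplyr::bind_rows(recs)
}

flip_labels <- function(labels, noise_rate, rng) {
  if (noise_rate <= 0) return(labels)
  flip <- rng$runif(length(labels)) < noise_rate
  ifelse(flip, 1L - labels, labels)
}

# residue-stratified sample of m records (shared by balance_negatives)
stratified_take <- function(records, m, rng) {
  counts <- vapply(STY, function(r) sum(records$residue == r), integer(1))
  frac <- m * counts / sum(counts)
  alloc <- floor(frac)
  rem <- m - sum(alloc)
  ord <- order(frac - alloc, decreasing = TRUE)
  for (i in ord) {
    if (rem == 0L) break
    if (counts[i] > alloc[i]) { alloc[i] <- alloc[i] + 1L; rem <- rem - 1L }
  }
  picked <- lapply(seq_along(STY), function(i) {
    pool <- which(records$residue == STY[i])
    pool[rng$sample_n(length(pool), alloc[i])]
  })
  records[sort(unlist(picked)), ]
}

#' Generate the synthetic functional-site dataset
#'
#' Enumerates every S/T/Y residue as a candidate, labels it by the motif
#' rule (then flips with probability `noise_rate`), samples the requested
#' number of positives and balances negatives by residue-stratified
#' sampling.
#'
#' @param cfg A [synth_config()].
#' @param proteins Proteins from [gen_proteins()].
#' @return A validated tibble of site records.
#' @export
gen_site_dataset <- function(cfg, proteins) {
  rng <- rng_local(derive_seed(cfg$seed, 2))
  cand <- candidate_sites(proteins, cfg)
  cand$label <- flip_labels(cand$label, cfg$noise_rate, rng)
  n_pos <- round(cfg$n_sites * cfg$positive_fraction_sites)
  n_neg <- cfg$n_sites - n_pos
  pos_pool <- cand[cand$label == 1L, ]
  neg_pool <- cand[cand$label == 0L, ]
  if (nrow(pos_pool) < n_pos || nrow(neg_pool) < n_neg) {
    stop(sprintf(
      "only %d motif-positive / %d negative candidates for %d/%d requested; increase n_proteins",
      nrow(pos_pool), nrow(neg_pool), n_pos, n_neg), call. = FALSE)
  }
  positives <- pos_pool[sort(rng$sample_n(nrow(pos_pool), n_pos)), ]
  negatives <- stratified_take(neg_pool, n_neg, rng)
  validate_sites(dplyr::bind_rows(positives, negatives), proteins)
}

#' Generate the synthetic interaction-effect dataset
#'
#' Samples protein pairs with a candidate S/T/Y site on partner A. The
#' effect label is enhancement iff the signal motif occurs near the site
#' (anywhere inside its 31-residue window) XOR the inhibitor trigram
#' occurs in B's first 20 residues, so the label depends on both proteins.
#' The motif and trigram states are sampled independently with base rates
#' solved so the XOR hits `enhancement_fraction` in expectation while each
#' single feature stays marginally informative (a model seeing only
#' protein A is capped at the accuracy the B-side trigram base rate
#' allows). Labels are then flipped with probability `noise_rate`.
#'
#' @inheritParams gen_site_dataset
#' @return A validated tibble of effect records.
#' @export
gen_ppi_dataset <- function(cfg, proteins) {
  rng <- rng_local(derive_seed(cfg$seed, 3))
  cand <- candidate_sites(proteins, cfg)
  near <- vapply(seq_len(nrow(cand)), function(i) {
    motif_near(proteins$sequence[match(cand$protein_id[i], proteins$id)],
               cand$position[i], cfg$signal_motif)
  }, logical(1))
  site_pool <- list(`0` = cand[!near, ], `1` = cand[near, ])
  trig <- vapply(proteins$sequence, has_inhibitor, logical(1),
                 trigram = cfg$inhibitor_trigram)
  b_pool <- list(`0` = proteins$id[!trig], `1` = proteins$id[trig])
  short <- c(nrow(site_pool[["0"]]) == 0L, nrow(site_pool[["1"]]) == 0L,
             length(b_pool[["0"]]) == 0L, length(b_pool[["1"]]) == 0L)
  if (any(short)) {
    stop("empty motif or inhibitor pool; increase n_proteins", call. = FALSE)
  }
  n <- cfg$n_pairs
  # independent base rates p_m (motif near site) and p_t (trigram in B)
  # with p_m (1 - p_t) + (1 - p_m) p_t = enhancement_fraction; fixing
  # p_m = max(f, 1 - f) gives p_t = (p_m - f) / (2 p_m - 1)
  f <- cfg$enhancement_fraction
  p_m <- min(max(f, 1 - f) + 0.1, 0.9)
  p_t <- (p_m - f) / (2 * p_m - 1)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    m <- as.integer(rng$rbinom1(p_m))
    t <- as.integer(rng$rbinom1(p_t))
    y <- as.integer(xor(m == 1L, t == 1L))
    pool <- site_pool[[as.character(m)]]
    s <- pool[rng$sample_n(nrow(pool), 1L), ]
    b_ids <- b_pool[[as.character(t)]]
    b <- rng$sample_vec(b_ids, 1L)
    if (b == s$protein_id && length(b_ids) > 1L) {
      while (b == s$protein_id) b <- rng$sample_vec(b_ids, 1L)
    }
    rows[[k]] <- tibble::tibble(protein_a_id = s$protein_id,
                                protein_b_id = b, position = s$position,
                                label = y)
  }
  pairs <- dplyr::bind_rows(rows)
  pairs$label <- flip_labels(pairs$label, cfg$noise_rate, rng)
  validate_pairs(pairs, proteins)
}

#' Write a complete synthetic study to disk
#'
#' Generates proteins, the site dataset and the effect dataset, and writes
#' FASTA, the two TSV tables and a JSON manifest recording the
#' configuration.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the three tibbles and the file paths.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  proteins <- gen_proteins(cfg)
  sites <- gen_site_dataset(cfg, proteins)
  pairs <- gen_ppi_dataset(cfg, proteins)
  paths <- list(fasta = file.path(dir, "proteins.fasta"),
                sites = file.path(dir, "sites.tsv"),
                pairs = file.path(dir, "pairs.tsv"),
                manifest = file.path(dir, "manifest.json"))
  write_fasta(proteins, paths$fasta)
  write_site_table(sites, paths$sites)
  write_ppi_table(pairs, paths$pairs)
  jsonlite::write_json(
    list(config = unclass(cfg), n_proteins = nrow(proteins),
         n_sites = nrow(sites), n_pairs = nrow(pairs),
         package_version = as.character(utils::packageVersion("phosppi")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(proteins = proteins, sites = sites, pairs = pairs,
                 paths = paths))
}
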