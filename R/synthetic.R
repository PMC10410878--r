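# Planted-motif synthetic sequence pairs.
#
# Emulates the statistical shape of the YY1 anchor-pair benchmark: fixed
# length pairs, near-balanced classes, and a learnable *pairwise* signal.
# Positives carry a compatible motif pair (a YY1-like site planted in each
# anchor, mirroring a YY1 dimer needing two bound sites); negatives carry at
# most one of the two motifs, so the label can only be predicted by
# combining both inputs. No attempt is made to simulate HiChIP contact
# counts or genomic background realism.

# Default planted 12-mers; both contain the ATGG/CCAT core of the YY1
# consensus. The alternative pair (for disjoint-condition transfer
# experiments) shares no 4-mer with the defaults on either strand, so a
# model trained on one condition finds no reusable substructure in the
# other.
.default_motifs <- list(a = "AAGATGGCGGCT", b = "CGCCATCTTGAC")
.alt_motifs <- list(a = "CAGCGAAGTAGT", b = "AATCGGTCCACC")

#' Simulate labeled sequence pairs with a planted pair signal
#'
#' Background sequences are drawn i.i.d. with the stated GC content.
#' Positive pairs carry a noisy copy of `motif_a` in `seq_a` and of
#' `motif_b` in `seq_b` (centered by default, matching anchors centered on
#' the YY1 motif). Negatives carry, if `decoy_in_negatives`, exactly one of
#' the two motifs (never the compatible pair) — so single-branch matching
#' cannot separate the classes — or no motif at all otherwise. Substitution
#' noise flips each motif base independently to a uniformly chosen
#' *different* base, making signal-strength expectations exact.
#'
#' @param n_pairs Number of pairs (>= 2).
#' @param seq_len Sequence length (default 506, the benchmark anchor width).
#' @param positive_fraction Fraction of loop-forming pairs (default 0.5,
#'   near-balanced like the benchmark).
#' @param motif_a,motif_b Planted DNA 12-mers (package defaults carry a
#'   YY1-like core).
#' @param plant_mode `"centered"` (default) or `"uniform"` random offsets.
#' @param noise_rate Per-base substitution probability in planted copies.
#' @param background_gc Background GC content.
#' @param decoy_in_negatives If `TRUE` (default) each negative carries one
#'   motif (A-side or B-side, coin flip) but never both.
#' @param seed RNG seed; the output is byte-identical for a seed.
#' @param condition_label Optional `cell_type` tag.
#' @return A validated pair tibble with ground-truth plant columns
#'   `planted_a`, `planted_b` (the noisy copies; `NA` where nothing was
#'   planted) and `pos_a`, `pos_b` (1-based plant offsets), carrying class
#'   `sim_pairs`.
#' @export
simulate_pairs <- function(n_pairs, seq_len = 506L, positive_fraction = 0.5,
                           motif_a = NULL, motif_b = NULL,
                           plant_mode = c("centered", "uniform"),
                           noise_rate = 0.1, background_gc = 0.5,
                           decoy_in_negatives = TRUE, seed = 1L,
                           condition_label = NULL) {
  plant_mode <- match.arg(plant_mode)
  motif_a <- toupper(motif_a %||% .default_motifs$a)
  motif_b <- toupper(motif_b %||% .default_motifs$b)
  n_pairs <- as.integer(n_pairs); seq_len <- as.integer(seq_len)
  if (n_pairs < 2L) stop("n_pairs must be >= 2", call. = FALSE)
  if (noise_rate < 0 || noise_rate > 1) {
    stop("noise_rate must be in [0, 1]", call. = FALSE)
  }
  if (background_gc < 0 || background_gc > 1) {
    stop("background_gc must be in [0, 1]", call. = FALSE)
  }
  if (positive_fraction < 0 || positive_fraction > 1) {
    stop("positive_fraction must be in [0, 1]", call. = FALSE)
  }
  if (max(nchar(motif_a), nchar(motif_b)) >= seq_len) {
    stop("motifs must be shorter than seq_len", call. = FALSE)
  }
  if (grepl("[^ACGT]", motif_a) || grepl("[^ACGT]", motif_b)) {
    stop("motifs must be over A,C,G,T", call. = FALSE)
  }
  n_pos <- as.integer(round(n_pairs * positive_fraction))
  n_neg <- n_pairs - n_pos
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - background_gc) / 2, background_gc / 2,
             background_gc / 2, (1 - background_gc) / 2)
  withr::with_seed(as.integer(seed), {
    draw_background <- function(n) {
      m <- matrix(sample(bases, n * seq_len, replace = TRUE, prob = probs),
                  nrow = n)
      do.call(paste0, lapply(base::seq_len(seq_len), function(j) m[, j]))
    }
    noisy_copy <- function(motif, n) {
      ml <- nchar(motif)
      chars <- matrix(strsplit(motif, "")[[1L]], nrow = n, ncol = ml,
                      byrow = TRUE)
      flip <- matrix(stats::runif(n * ml) < noise_rate, nrow = n)
      if (any(flip)) {
        idx <- which(flip)
        orig <- chars[idx]
        # substitution excludes the original base
        repl <- vapply(orig, function(b) sample(setdiff(bases, b), 1L),
                       character(1L))
        chars[idx] <- repl
      }
      do.call(paste0, lapply(base::seq_len(ml), function(j) chars[, j]))
    }
    plant_pos <- function(motif, n) {
      ml <- nchar(motif)
      if (plant_mode == "centered") {
        rep.int(as.integer(floor((seq_len - ml) / 2) + 1L), n)
      } else {
        sample.int(seq_len - ml + 1L, n, replace = TRUE)
      }
    }
    plant <- function(seqs, copies, pos) {
      substr(seqs, pos, pos + nchar(copies) - 1L) <- copies
      seqs
    }
    label <- sample(rep(c(1L, 0L), c(n_pos, n_neg)))
    seq_a <- draw_background(n_pairs)
    seq_b <- draw_background(n_pairs)
    planted_a <- rep(NA_character_, n_pairs)
    planted_b <- rep(NA_character_, n_pairs)
    pos_a <- rep(NA_integer_, n_pairs)
    pos_b <- rep(NA_integer_, n_pairs)
    ipos <- which(label == 1L)
    if (length(ipos) > 0L) {
      planted_a[ipos] <- noisy_copy(motif_a, length(ipos))
      planted_b[ipos] <- noisy_copy(motif_b, length(ipos))
      pos_a[ipos] <- plant_pos(motif_a, length(ipos))
      pos_b[ipos] <- plant_pos(motif_b, length(ipos))
      seq_a[ipos] <- plant(seq_a[ipos], planted_a[ipos], pos_a[ipos])
      seq_b[ipos] <- plant(seq_b[ipos], planted_b[ipos], pos_b[ipos])
    }
    ineg <- which(label == 0L)
    if (decoy_in_negatives && length(ineg) > 0L) {
      side <- sample(c("a", "b"), length(ineg), replace = TRUE)
      ia <- ineg[side == "a"]; ib <- ineg[side == "b"]
      if (length(ia) > 0L) {
        planted_a[ia] <- noisy_copy(motif_a, length(ia))
        pos_a[ia] <- plant_pos(motif_a, length(ia))
        seq_a[ia] <- plant(seq_a[ia], planted_a[ia], pos_a[ia])
      }
      if (length(ib) > 0L) {
        planted_b[ib] <- noisy_copy(motif_b, length(ib))
        pos_b[ib] <- plant_pos(motif_b, length(ib))
        seq_b[ib] <- plant(seq_b[ib], planted_b[ib], pos_b[ib])
      }
    }
    out <- tibble::tibble(
      id = sprintf("pair_%05d", base::seq_len(n_pairs)),
      seq_a = seq_a, seq_b = seq_b, label = label,
      planted_a = planted_a, planted_b = planted_b,
      pos_a = pos_a, pos_b = pos_b
    )
    if (!is.null(condition_label)) out$cell_type <- condition_label
    out <- validate_pairs(out)
    attr(out, "sim") <- list(motif_a = motif_a, motif_b = motif_b,
                             noise_rate = noise_rate, seed = as.integer(seed),
                             plant_mode = plant_mode,
                             decoy_in_negatives = decoy_in_negatives,
                             background_gc = background_gc)
    class(out) <- c("sim_pairs", class(out))
    out
  })
}

#' Simulate a two-condition ("cell type") dataset pair
#'
#' Supports the cross-cell transfer experiment: with `shared_motifs = TRUE`
#' the two conditions plant the same motif pair (transfer should succeed);
#' with `FALSE` they plant disjoint motif pairs (transfer should fail while
#' each model still separates its own condition).
#'
#' @param n_pairs Pairs per condition.
#' @param shared_motifs Share the planted motif pair across conditions?
#' @param condition_labels Length-2 character vector of condition names.
#' @param seed Master seed; per-condition seeds derive from it.
#' @param ... Passed to [simulate_pairs()] (e.g. `seq_len`, `noise_rate`).
#' @return A named list of two `sim_pairs` tibbles.
#' @export
simulate_condition_pair <- function(n_pairs, shared_motifs = TRUE,
                                    condition_labels = c("cellA", "cellB"),
                                    seed = 1L, ...) {
  stopifnot(length(condition_labels) == 2L)
  motifs2 <- if (shared_motifs) .default_motifs else .alt_motifs
  out <- list(
    simulate_pairs(n_pairs, motif_a = .default_motifs$a,
                   motif_b = .default_motifs$b,
                   seed = derive_seed(seed, condition_labels[1L]),
                   condition_label = condition_labels[1L], ...),
    simulate_pairs(n_pairs, motif_a = motifs2$a, motif_b = motifs2$b,
                   seed = derive_seed(seed, condition_labels[2L]),
                   condition_label = condition_labels[2L], ...)
  )
  names(out) <- condition_labels
  out
}

#' Realized signal strength of a simulated dataset
#'
#' Per class, compares each planted (noisy) motif copy with the clean motif:
#' exact-match fraction and mean Hamming distance, so tests can assert the
#' generated difficulty (mean Hamming is Binomial(motif length, noise rate)
#' in expectation).
#'
#' @param pairs A `sim_pairs` tibble from [simulate_pairs()].
#' @return A tibble with one row per (class, branch) that planted anything:
#'   `label`, `branch`, `n_planted`, `exact_match_fraction`,
#'   `mean_hamming`.
#' @export
signal_strength <- function(pairs) {
  sim <- attr(pairs, "sim")
  if (is.null(sim)) stop("not a simulated dataset (no plant records)",
                         call. = FALSE)
  hamming <- function(x, motif) {
    ref <- strsplit(motif, "")[[1L]]
    vapply(strsplit(x, ""), function(ch) sum(ch != ref), numeric(1L))
  }
  rows <- list()
  for (branch in c("a", "b")) {
    planted <- pairs[[paste0("planted_", branch)]]
    motif <- sim[[paste0("motif_", branch)]]
    for (lab in c(0L, 1L)) {
      sel <- pairs$label == lab & !is.na(planted)
      if (!any(sel)) next
      h <- hamming(planted[sel], motif)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        label = lab, branch = branch, n_planted = sum(sel),
        exact_match_fraction = mean(h == 0), mean_hamming = mean(h)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Minimum Hamming distance of a motif over all windows of each sequence
#'
#' Utility used to show the planted signal is learnable independently of the
#' neural model: a trivial matcher scoring pairs by
#' `-(min_hamming(seq_a, motif_a) + min_hamming(seq_b, motif_b))` separates
#' simulated classes.
#'
#' @param seqs Character vector of equal-length DNA sequences.
#' @param motif A DNA motif string.
#' @return Integer vector of per-sequence minimum Hamming distances.
#' @export
motif_min_hamming <- function(seqs, motif) {
  L <- nchar(seqs[1L]); m <- nchar(motif)
  stopifnot(all(nchar(seqs) == L), m <= L)
  chars <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE)
  ref <- strsplit(motif, "")[[1L]]
  best <- rep.int(m, length(seqs))
  for (off in 0:(L - m)) {
    d <- integer(length(seqs))
    for (j in seq_len(m)) d <- d + (chars[, off + j] != ref[j])
    best <- pmin(best, d)
  }
  as.integer(best)
}

#' Write the plant-record sidecar of a simulated dataset
#'
#' Stores the generator settings and per-pair ground truth as JSON next to
#' the TSV pair table emitted by [write_pairs()].
#'
#' @param pairs A `sim_pairs` tibble.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sim_sidecar <- function(pairs, path) {
  sim <- attr(pairs, "sim")
  if (is.null(sim)) stop("not a simulated dataset", call. = FALSE)
  records <- pairs[c("id", "label", "planted_a", "pos_a", "planted_b", "pos_b")]
  jsonlite::write_json(list(config = sim, records = records), path,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
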