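#' Specification for a stop-codon-to-terminator spacer
#'
#' Design rules for the spacer inserted between a stop codon and a terminator
#' hairpin: low GC content and short G/C runs (so the spacer itself folds
#' poorly), and no k-mer complementary to the terminator hairpin arms or to
#' the spacer itself (so it cannot compete with hairpin folding). Secondary
#' structure is screened by complementary-k-mer matching, a deliberate proxy
#' for thermodynamic folding; a full MFE folder can be plugged in behind the
#' same report interface.
#'
#' @param length Spacer length in nt (>= 1).
#' @param max_gc_fraction Maximal GC fraction (0, 1].
#' @param max_gc_run Longest allowed run of consecutive G/C bases.
#' @param kmer_k k-mer size for the complementarity screen (<= length).
#' @param forbidden_complement_targets Character vector of sequences (e.g.
#'   the two hairpin arms) whose reverse complements must not appear in the
#'   spacer.
#' @param max_attempts Rejection-sampling budget for [design_spacer()].
#' @param seed Integer seed.
#' @return A list of class `spacer_spec`.
#' @export
spacer_spec <- function(length, max_gc_fraction = 0.5, max_gc_run = 3,
                        kmer_k = 6, forbidden_complement_targets = character(),
                        max_attempts = 10000, seed = 1) {
  stopifnot(length >= 1, length == round(length),
            max_gc_fraction > 0, max_gc_fraction <= 1,
            max_gc_run >= 1, kmer_k >= 1, kmer_k <= length,
            max_attempts >= 1)
  targets <- toupper(forbidden_complement_targets)
  if (length(targets) > 0 && any(grepl("[^ACGT]", targets))) {
    abort("forbidden targets must be DNA over {A,C,G,T}.")
  }
  structure(
    list(length = as.integer(length), max_gc_fraction = max_gc_fraction,
         max_gc_run = as.integer(max_gc_run), kmer_k = as.integer(kmer_k),
         forbidden_complement_targets = targets,
         max_attempts = as.integer(max_attempts), seed = as.integer(seed)),
    class = "spacer_spec"
  )
}

.revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

#' Screen a sequence against spacer design rules
#'
#' Pure predicate evaluation (no randomness) of the GC-fraction, GC-run, and
#' complementary-k-mer screens, plus a heuristic warning for internal
#' translation-initiation sites (a Shine-Dalgarno-like AGGAGG motif followed
#' by ATG at 4-12 nt).
#'
#' @param seq A DNA sequence over {A,C,G,T}.
#' @param spec A [spacer_spec()].
#' @return A tibble (one row per screen): `screen`, `pass`, `detail`. The
#'   overall verdict is `all(pass)` over non-warning rows; an attribute
#'   `pass` carries it.
#' @export
screen_sequence <- function(seq, spec) {
  stopifnot(inherits(spec, "spacer_spec"), is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) abort("sequence must be DNA over {A,C,G,T}.")
  chars <- strsplit(seq, "")[[1]]

  gc_frac <- mean(chars %in% c("G", "C"))
  gc_ok <- gc_frac <= spec$max_gc_fraction

  runs <- rle(chars %in% c("G", "C"))
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  run_ok <- max_run <= spec$max_gc_run

  kms <- .kmers(seq, spec$kmer_k)
  rc <- .revcomp(kms)
  hit_target <- character(0)
  for (target in spec$forbidden_complement_targets) {
    bad <- kms[vapply(rc, function(r) grepl(r, target, fixed = TRUE), TRUE)]
    hit_target <- c(hit_target, bad)
  }
  # self-structure proxy: a k-mer whose reverse complement occurs downstream
  # in the spacer with a foldable loop (>= 3 nt between the arms)
  k <- spec$kmer_k
  self_bad <- kms[vapply(seq_along(kms), function(i) {
    hits <- gregexpr(rc[i], seq, fixed = TRUE)[[1]]
    any(hits >= i + k + 3)
  }, TRUE)]
  kmer_ok <- length(hit_target) == 0 && length(self_bad) == 0

  sd_hit <- regexpr("AGGAGG", seq, fixed = TRUE)
  sd_warn <- FALSE
  if (sd_hit > 0) {
    downstream <- substring(seq, sd_hit + 6 + 4, sd_hit + 6 + 12 + 2)
    sd_warn <- grepl("ATG", downstream, fixed = TRUE)
  }

  report <- tibble::tibble(
    screen = c("gc_fraction", "gc_run", "kmer_complementarity", "sd_motif_warning"),
    pass = c(gc_ok, run_ok, kmer_ok, !sd_warn),
    detail = c(
      sprintf("GC fraction %.3f (max %.3f)", gc_frac, spec$max_gc_fraction),
      sprintf("longest G/C run %d (max %d)", max_run, spec$max_gc_run),
      if (kmer_ok) "no complementary k-mers" else
        sprintf("offending k-mers: %s",
                paste(unique(c(hit_target, self_bad)), collapse = ", ")),
      if (sd_warn) "AGGAGG-like motif with downstream ATG (possible internal initiation site)"
      else "no internal initiation motif"
    ),
    fatal = c(TRUE, TRUE, TRUE, FALSE)
  )
  attr(report, "pass") <- all(report$pass[report$fatal])
  report
}

#' Design a spacer sequence by rejection sampling
#'
#' Draws uniform random DNA of the specified length and accepts the first
#' sequence passing every fatal screen in [screen_sequence()]. Deterministic
#' given the spec's seed.
#'
#' @param spec A [spacer_spec()].
#' @return A list of class `spacer_design`: `sequence`, `report` (the
#'   accepted sequence's screen report), `attempts`.
#' @export
design_spacer <- function(spec) {
  stopifnot(inherits(spec, "spacer_spec"))
  set.seed(spec$seed)
  fail_counts <- c(gc_fraction = 0L, gc_run = 0L, kmer_complementarity = 0L)
  for (attempt in seq_len(spec$max_attempts)) {
    seq <- paste(sample(c("A", "C", "G", "T"), spec$length, replace = TRUE),
                 collapse = "")
    report <- screen_sequence(seq, spec)
    if (attr(report, "pass")) {
      return(structure(
        list(sequence = seq, report = report, attempts = attempt),
        class = "spacer_design"
      ))
    }
    failed <- report$screen[report$fatal & !report$pass]
    fail_counts[failed] <- fail_counts[failed] + 1L
  }
  tightest <- names(which.max(fail_counts))
  abort(sprintf(
    "constraints unsatisfiable: no sequence accepted in %d attempts (tightest screen: %s, failed %d times)",
    spec$max_attempts, tightest, max(fail_counts)
  ))
}

#' @export
print.spacer_design <- function(x, ...) {
  cat(sprintf("Spacer (%d nt, accepted after %d attempt%s)\n",
              nchar(x$sequence), x$attempts, if (x$attempts == 1) "" else "s"))
  cat(" ", x$sequence, "\n")
  invisible(x)
}

#' Read hairpin-arm sequences from a FASTA file
#'
#' @param path Path to a FASTA file of terminator hairpin arms (or any
#'   sequences to forbid complementarity with).
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta_targets <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package.")
  }
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(set)), names(set))
}

#' Write designed spacers to a FASTA file
#'
#' @param designs A `spacer_design` or list of them.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_spacer_fasta <- function(designs, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("writing FASTA requires the Biostrings package.")
  }
  if (inherits(designs, "spacer_design")) designs <- list(designs)
  seqs <- vapply(designs, function(d) d$sequence, "")
  names(seqs) <- sprintf("spacer_%d_len%d", seq_along(seqs), nchar(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
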