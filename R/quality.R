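#' Minimum-edit-distance word alignment
#'
#' Aligns a hypothesis word sequence against a reference with unit costs
#' for substitution, deletion and insertion, and returns the hit,
#' substitution, deletion and insertion counts of an optimal alignment.
#' Among equal-cost alignments the backtrace prefers hits, then
#' substitutions, then deletions (the metric values are tie-invariant; the
#' preference only makes the counts deterministic). The conservation
#' identities `H + S + D = N_ref` and `H + S + I = N_hyp` always hold.
#'
#' Inputs are compared verbatim; pass tokens produced by [tokenize()] so
#' that case and punctuation differences do not count as word errors.
#'
#' @param reference reference token vector (or `transcript`); non-empty.
#' @param hypothesis hypothesis token vector (or `transcript`); may be
#'   empty.
#' @return object of class `alignment_counts`: named list `hits`,
#'   `substitutions`, `deletions`, `insertions`, `n_ref`, `n_hyp`.
#' @export
#' @examples
#' align(c("the", "cat", "sat"), c("the", "cat"))
align <- function(reference, hypothesis) {
  ref <- if (inherits(reference, "transcript")) reference$tokens_flat
         else as.character(reference)
  hyp <- if (inherits(hypothesis, "transcript")) hypothesis$tokens_flat
         else as.character(hypothesis)
  nr <- length(ref); nh <- length(hyp)
  if (nr == 0) stop("undefined metric: reference is empty")
  # DP over the (nr+1) x (nh+1) cost lattice, row-vectorized: the
  # insertion recurrence min_k w[k] + (j - k) equals j + cummin(w - j).
  D <- matrix(0, nr + 1, nh + 1)
  D[1, ] <- 0:nh
  D[, 1] <- 0:nr
  if (nh > 0) {
    jj <- seq_len(nh)
    for (i in seq_len(nr)) {
      sub <- D[i, jj] + (ref[i] != hyp)
      del <- D[i, jj + 1] + 1
      w <- c(D[i + 1, 1], pmin(sub, del))
      D[i + 1, ] <- 0:nh + cummin(w - 0:nh)
    }
  }
  # backtrace with tie preference hit > substitution > deletion > insertion
  H <- S <- Del <- Ins <- 0L
  i <- nr; j <- nh
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && ref[i] == hyp[j] && D[i + 1, j + 1] == D[i, j]) {
      H <- H + 1L; i <- i - 1; j <- j - 1
    } else if (i > 0 && j > 0 && D[i + 1, j + 1] == D[i, j] + 1) {
      S <- S + 1L; i <- i - 1; j <- j - 1
    } else if (i > 0 && D[i + 1, j + 1] == D[i, j + 1] + 1) {
      Del <- Del + 1L; i <- i - 1
    } else {
      Ins <- Ins + 1L; j <- j - 1
    }
  }
  structure(list(hits = H, substitutions = S, deletions = Del,
                 insertions = Ins, n_ref = nr, n_hyp = nh),
            class = "alignment_counts")
}

#' @export
print.alignment_counts <- function(x, ...) {
  cat(sprintf("<alignment: H=%d S=%d D=%d I=%d (ref %d, hyp %d)>\n",
              x$hits, x$substitutions, x$deletions, x$insertions,
              x$n_ref, x$n_hyp))
  invisible(x)
}

#' Transcription quality metrics from alignment counts
#'
#' Word Error Rate `WER = (S + D + I) / N_ref`, Match Error Rate
#' `MER = (S + D + I) / (H + S + D + I)`, and Word Information Lost
#' `WIL = 1 - H^2 / (N_ref * N_hyp)`. Lower is better; MER and WIL lie in
#' \[0, 1\], WER can exceed 1. An empty hypothesis gives `WIL = 1` by
#' definition.
#'
#' @param counts an [align()] result, or the two sequences via `reference`
#'   and `hypothesis` arguments of [align()].
#' @return named numeric vector `wer`, `mer`, `wil`.
#' @export
#' @examples
#' quality_metrics(align(c("the", "cat", "sat"), c("the", "cat")))
quality_metrics <- function(counts) {
  stopifnot(inherits(counts, "alignment_counts"))
  err <- counts$substitutions + counts$deletions + counts$insertions
  wer <- err / counts$n_ref
  mer <- err / (counts$hits + err)
  wil <- if (counts$n_hyp == 0) {
    message("empty hypothesis: WIL = 1 by definition")
    1
  } else {
    1 - as.numeric(counts$hits)^2 /
      (as.numeric(counts$n_ref) * as.numeric(counts$n_hyp))
  }
  c(wer = wer, mer = mer, wil = wil)
}

#' Manual-vs-automated transcription quality of a cohort
#'
#' Aligns every automated transcript against its manual counterpart and
#' reports quality at three levels: per excerpt, per participant
#' (macro-average of the participant's excerpt-level metrics, mirroring the
#' marker aggregation rule), and corpus-wide (micro-average: error counts
#' pooled before dividing).
#'
#' @param cohort a `speech_cohort` (see [gen_cohort()]) or a named list
#'   pairing, per key, `list(manual = transcript, automated = transcript)`.
#' @return object of class `corpus_quality`: list with data.frames
#'   `per_excerpt`, `per_participant`, and the named vector `corpus`.
#' @export
corpus_quality <- function(cohort) {
  pairs <- .transcript_pairs(cohort)
  n <- length(pairs)
  if (n == 0) stop("no manual/automated transcript pairs found")
  per <- vector("list", n)
  for (k in seq_len(n)) {
    pr <- pairs[[k]]
    cts <- align(pr$manual, pr$automated)
    per[[k]] <- data.frame(participant_id = pr$manual$participant_id,
                           excerpt_id = pr$manual$excerpt_id,
                           hits = cts$hits, substitutions = cts$substitutions,
                           deletions = cts$deletions,
                           insertions = cts$insertions,
                           n_ref = cts$n_ref, n_hyp = cts$n_hyp,
                           t(quality_metrics(cts)),
                           stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  by_p <- split(per, per$participant_id)
  per_participant <- do.call(rbind, lapply(by_p, function(d) {
    data.frame(participant_id = d$participant_id[1], n_excerpts = nrow(d),
               wer = mean(d$wer), mer = mean(d$mer), wil = mean(d$wil),
               stringsAsFactors = FALSE)
  }))
  rownames(per_participant) <- NULL
  pooled <- structure(list(hits = sum(per$hits),
                           substitutions = sum(per$substitutions),
                           deletions = sum(per$deletions),
                           insertions = sum(per$insertions),
                           n_ref = sum(per$n_ref), n_hyp = sum(per$n_hyp)),
                      class = "alignment_counts")
  structure(list(per_excerpt = per, per_participant = per_participant,
                 corpus = quality_metrics(pooled)),
            class = "corpus_quality")
}

#' @export
print.corpus_quality <- function(x, ...) {
  cat(sprintf("<corpus_quality: %d excerpts, %d participants>\n",
              nrow(x$per_excerpt), nrow(x$per_participant)))
  cat(sprintf("  corpus (micro): WER %.3f  MER %.3f  WIL %.3f\n",
              x$corpus["wer"], x$corpus["mer"], x$corpus["wil"]))
  cat(sprintf("  participant macro-mean WER %.3f\n",
              mean(x$per_participant$wer)))
  invisible(x)
}

.transcript_pairs <- function(cohort) {
  trs <- if (inherits(cohort, "speech_cohort")) cohort$transcripts else cohort
  if (inherits(cohort, "speech_cohort") || all(vapply(trs, inherits,
                                                      logical(1),
                                                      "transcript"))) {
    # flat named list of transcripts: pair by participant/excerpt
    key <- vapply(trs, function(t) paste(t$participant_id, t$excerpt_id,
                                         sep = "/"), character(1))
    ver <- vapply(trs, function(t) t$version, character(1))
    out <- list()
    for (k in unique(key)) {
      m <- trs[key == k & ver == "manual"]
      a <- trs[key == k & ver == "automated"]
      if (length(m) == 1 && length(a) == 1) {
        out[[k]] <- list(manual = m[[1]], automated = a[[1]])
      }
    }
    out
  } else {
    trs
  }
}

#' Manual-vs-automated marker agreement
#'
#' Spearman rank correlation, per marker, between the participant-level
#' marker means of the manual and the automated transcript versions. A
#' marker that is constant in either version yields a missing correlation
#' (with a message) rather than a fabricated value.
#'
#' @param features participant-level feature table with columns
#'   `participant_id`, `version`, and one column per marker (see
#'   [aggregate_participants()]).
#' @return data.frame with columns `marker`, `n`, `rho`, `p`.
#' @export
marker_agreement <- function(features) {
  stopifnot(is.data.frame(features),
            all(c("participant_id", "version") %in% names(features)))
  markers <- setdiff(names(features), c("participant_id", "version"))
  man <- features[features$version == "manual", , drop = FALSE]
  aut <- features[features$version == "automated", , drop = FALSE]
  common <- intersect(man$participant_id, aut$participant_id)
  if (length(common) < 3) stop("need both versions for at least 3 participants")
  man <- man[match(common, man$participant_id), , drop = FALSE]
  aut <- aut[match(common, aut$participant_id), , drop = FALSE]
  res <- lapply(markers, function(mk) {
    x <- man[[mk]]; y <- aut[[mk]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      message("marker_agreement: constant or insufficient marker '", mk,
              "', correlation reported missing")
      return(data.frame(marker = mk, n = length(x), rho = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    data.frame(marker = mk, n = length(x), rho = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
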