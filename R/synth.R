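# Seed-reproducible synthetic report generator: planted diagnostic
# groups with group-exclusive marker vocabularies in both the diagnosis
# and the description section, a shared background vocabulary mixed in
# with weight `overlap`, power-law group sizes, per-author function-word
# styles, outlier documents drawn from background only, and malformed
# reports that lack a required section tag. Ground truth is returned
# alongside, so every pipeline stage can be tested against known labels.

#' Specification of a synthetic report corpus
#'
#' @param K Number of planted diagnostic groups.
#' @param n_docs Total report count (ignored when `sizes` is given).
#' @param sizes Optional explicit per-group document counts.
#' @param size_exponent Power-law exponent for the group-size profile
#'   (default 1.5: a long-tailed, imbalanced case mix).
#' @param size_floor Minimum documents per group (default 8).
#' @param vocab_size Total vocabulary size across background, marker and
#'   author terms.
#' @param markers_per_group Group-exclusive terms per group and section
#'   type (diagnosis and description markers are separate sets).
#' @param overlap Mixing weight in `[0, 1]`: each content token comes
#'   from the shared background distribution with probability `overlap`,
#'   else from the group's marker distribution. 0 = disjoint group
#'   vocabularies, 1 = no group signal.
#' @param doc_length_mean Named mean token counts per section
#'   (`diagnosis`, `microscopy`, `clinical`).
#' @param n_authors Number of report authors.
#' @param author_token_rate Fraction of tokens replaced by the author's
#'   function words (style signal).
#' @param author_cluster_bias In `[0, 1]`: 0 = authors independent of
#'   groups; 1 = each group written by a fixed author.
#' @param malformed_fraction Fraction of reports missing a required
#'   section tag (these cannot be segmented).
#' @param outlier_fraction Fraction of reports drawn from background
#'   only (no group membership).
#' @param coupling Probability that the description section is drawn
#'   from the same group as the diagnosis section (else from a random
#'   group); 1 = fully informative descriptions, 0 = uninformative.
#' @param seed Integer seed.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(K = 12L, n_docs = 600L, sizes = NULL,
                       size_exponent = 1.5, size_floor = 8L,
                       vocab_size = 2000L, markers_per_group = 25L,
                       overlap = 0,
                       doc_length_mean = c(diagnosis = 40, microscopy = 70,
                                           clinical = 12),
                       n_authors = 3L, author_token_rate = 0.1,
                       author_cluster_bias = 0,
                       malformed_fraction = 0, outlier_fraction = 0,
                       coupling = 1, seed = 1L) {
  fracs <- c(overlap = overlap, author_cluster_bias = author_cluster_bias,
             malformed_fraction = malformed_fraction,
             outlier_fraction = outlier_fraction, coupling = coupling)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  }
  if (is.null(sizes)) {
    w <- seq_len(K)^(-size_exponent)
    sizes <- pmax(size_floor, round(n_docs * w / sum(w)))
    sizes[1] <- sizes[1] + (n_docs - sum(sizes)) # absorb rounding drift
    if (sizes[1] < size_floor) stop("n_docs too small for K and size_floor")
  } else {
    K <- length(sizes)
    n_docs <- sum(sizes)
  }
  fw_per_author <- 12L
  n_special <- 2L * K * markers_per_group + n_authors * fw_per_author
  if (n_special >= vocab_size) {
    stop("marker and author terms (", n_special,
         ") exceed the vocabulary size (", vocab_size, ")")
  }
  structure(
    list(K = as.integer(K), n_docs = as.integer(n_docs),
         sizes = as.integer(sizes), vocab_size = as.integer(vocab_size),
         markers_per_group = as.integer(markers_per_group),
         overlap = overlap, doc_length_mean = doc_length_mean,
         n_authors = as.integer(n_authors),
         author_token_rate = author_token_rate,
         author_fw_per_author = fw_per_author,
         author_cluster_bias = author_cluster_bias,
         malformed_fraction = malformed_fraction,
         outlier_fraction = outlier_fraction,
         coupling = coupling, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# Zipf-like weights over k items.
zipf_probs <- function(k, s = 1) {
  w <- seq_len(k)^(-s)
  w / sum(w)
}

synth_vocab <- function(spec) {
  K <- spec$K; mpg <- spec$markers_per_group
  list(
    dx_markers = lapply(seq_len(K) - 1L, function(g) {
      sprintf("grp%d_dx_%02d", g, seq_len(mpg))
    }),
    mx_markers = lapply(seq_len(K) - 1L, function(g) {
      sprintf("grp%d_mx_%02d", g, seq_len(mpg))
    }),
    author_fw = lapply(seq_len(spec$n_authors) - 1L, function(a) {
      sprintf("auth%d_fw_%02d", a, seq_len(spec$author_fw_per_author))
    }),
    background = sprintf("bg_%04d", seq_len(
      spec$vocab_size - 2L * K * mpg -
        spec$n_authors * spec$author_fw_per_author
    ))
  )
}

# Draw one section's tokens: group markers vs background, then author
# style words splice in.
draw_section <- function(n_tok, markers, marker_p, background, bg_p,
                         overlap, author_words, author_rate) {
  from_bg <- stats::runif(n_tok) < overlap
  toks <- character(n_tok)
  if (any(!from_bg)) {
    toks[!from_bg] <- sample(markers, sum(!from_bg), replace = TRUE,
                             prob = marker_p)
  }
  if (any(from_bg)) {
    toks[from_bg] <- sample(background, sum(from_bg), replace = TRUE,
                            prob = bg_p)
  }
  if (!is.null(author_words) && author_rate > 0) {
    style <- stats::runif(n_tok) < author_rate
    if (any(style)) {
      toks[style] <- sample(author_words, sum(style), replace = TRUE)
    }
  }
  toks
}

#' Generate a synthetic report corpus with ground truth
#'
#' @param spec A [synth_spec()].
#' @return List with `raw_reports` (list of [raw_report()]s carrying
#'   German section tags), `truth` (`data.frame`: `id`, `group` — `NA`
#'   for outliers —, `author`, `is_outlier`, `is_malformed`), `spec` and
#'   `vocab`.
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  vocab <- synth_vocab(spec)
  marker_p <- zipf_probs(spec$markers_per_group, 0.8)
  bg_p <- zipf_probs(length(vocab$background), 1.0)

  groups <- rep(seq_len(spec$K) - 1L, spec$sizes)
  n <- spec$n_docs
  with_local_seed(spec$seed, {
    groups <- sample(groups) # shuffle document order
    is_outlier <- stats::runif(n) < spec$outlier_fraction
    is_malformed <- stats::runif(n) < spec$malformed_fraction
    group_author <- (seq_len(spec$K) - 1L) %% spec$n_authors
    authors <- ifelse(
      !is_outlier & stats::runif(n) < spec$author_cluster_bias,
      group_author[groups + 1L],
      sample.int(spec$n_authors, n, replace = TRUE) - 1L
    )
    lens <- lapply(c(diagnosis = "diagnosis", microscopy = "microscopy",
                     clinical = "clinical"), function(sec) {
      pmax(3L, stats::rpois(n, spec$doc_length_mean[[sec]]))
    })

    reports <- vector("list", n)
    for (i in seq_len(n)) {
      g <- groups[i]
      a_words <- vocab$author_fw[[authors[i] + 1L]]
      dx <- if (is_outlier[i]) {
        draw_section(lens$diagnosis[i], vocab$background, bg_p,
                     vocab$background, bg_p, 1, a_words,
                     spec$author_token_rate)
      } else {
        draw_section(lens$diagnosis[i], vocab$dx_markers[[g + 1L]],
                     marker_p, vocab$background, bg_p, spec$overlap,
                     a_words, spec$author_token_rate)
      }
      mx_group <- if (is_outlier[i]) {
        NA_integer_
      } else if (stats::runif(1) < spec$coupling) {
        g
      } else {
        sample.int(spec$K, 1) - 1L
      }
      mx <- if (is.na(mx_group)) {
        draw_section(lens$microscopy[i], vocab$background, bg_p,
                     vocab$background, bg_p, 1, a_words,
                     spec$author_token_rate)
      } else {
        draw_section(lens$microscopy[i], vocab$mx_markers[[mx_group + 1L]],
                     marker_p, vocab$background, bg_p, spec$overlap,
                     a_words, spec$author_token_rate)
      }
      cl <- sample(vocab$background, lens$clinical[i], replace = TRUE,
                   prob = bg_p)
      drop_tag <- if (is_malformed[i]) sample(c("microscopy", "diagnosis"), 1)
                  else "none"
      txt <- c("Klinische Angaben:", paste(cl, collapse = " "))
      txt <- c(txt,
               if (drop_tag != "microscopy") "Mikroskopie:",
               paste(mx, collapse = " "))
      txt <- c(txt,
               if (drop_tag != "diagnosis") "Beurteilung:",
               paste(dx, collapse = " "))
      reports[[i]] <- raw_report(
        id = sprintf("doc%04d", i),
        text = paste(txt, collapse = "\n"),
        authors = sprintf("A%d", authors[i])
      )
    }
    truth <- data.frame(
      id = vapply(reports, `[[`, character(1), "id"),
      group = ifelse(is_outlier, NA_integer_, groups),
      author = sprintf("A%d", authors),
      is_outlier = is_outlier,
      is_malformed = is_malformed,
      stringsAsFactors = FALSE
    )
    list(raw_reports = reports, truth = truth, spec = spec, vocab = vocab)
  })
}

#' Audit a generated corpus against its specification
#'
#' Chi-square goodness of fit of the per-group marker frequencies in the
#' diagnosis sections against the generating distribution (conditioning
#' on marker terms, which background noise never emits), and binomial
#' 99% bounds on the malformed and outlier counts.
#'
#' @param generated Output of [synth_generate()].
#' @return List with `group_fit` (`data.frame`: `group`, `p_value`,
#'   `pass`), `frac_groups_pass`, `malformed_ok`, `outlier_ok` and the
#'   corresponding count bounds.
#' @export
synth_audit <- function(generated) {
  spec <- generated$spec
  vocab <- generated$vocab
  truth <- generated$truth
  marker_p <- zipf_probs(spec$markers_per_group, 0.8)
  texts <- vapply(generated$raw_reports, `[[`, character(1), "text")
  fits <- lapply(seq_len(spec$K) - 1L, function(g) {
    rows <- which(!truth$is_outlier & truth$group == g)
    if (length(rows) == 0) return(NULL)
    toks <- unlist(strsplit(paste(texts[rows], collapse = " "),
                            "[[:space:]]+"))
    markers <- vocab$dx_markers[[g + 1L]]
    obs <- table(factor(toks[toks %in% markers], levels = markers))
    if (sum(obs) < 5 * length(markers)) {
      # merge the zipf tail so expected counts stay reasonable
      keep <- seq_len(min(10L, length(markers)))
      obs <- c(obs[keep], sum(obs[-keep]))
      p <- c(marker_p[keep], sum(marker_p[-keep]))
    } else {
      p <- marker_p
    }
    pv <- suppressWarnings(stats::chisq.test(obs, p = p)$p.value)
    data.frame(group = g, p_value = pv, pass = pv >= 0.01)
  })
  group_fit <- do.call(rbind, fits)
  binom_bounds <- function(frac) {
    stats::qbinom(c(0.005, 0.995), spec$n_docs, frac)
  }
  mb <- binom_bounds(spec$malformed_fraction)
  ob <- binom_bounds(spec$outlier_fraction)
  n_mal <- sum(truth$is_malformed)
  n_out <- sum(truth$is_outlier)
  list(
    group_fit = group_fit,
    frac_groups_pass = mean(group_fit$pass),
    malformed_count = n_mal, malformed_bounds = mb,
    malformed_ok = n_mal >= mb[1] && n_mal <= mb[2],
    outlier_count = n_out, outlier_bounds = ob,
    outlier_ok = n_out >= ob[1] && n_out <= ob[2]
  )
}

#' Write a generated synthetic corpus to disk
#'
#' One text file per report plus a `ground_truth.tsv` sidecar.
#'
#' @param generated Output of [synth_generate()].
#' @param dir Output directory.
#' @export
synth_write <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in generated$raw_reports) {
    writeLines(r$text, file.path(dir, paste0(r$id, ".txt")),
               useBytes = TRUE)
  }
  utils::write.table(generated$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
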