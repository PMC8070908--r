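#' Chi-square goodness-of-fit test for segregation ratios
#'
#' Tests observed dominant/recessive phenotype counts against candidate
#' Mendelian ratios using the plain Pearson chi-square with 1 degree of
#' freedom (no continuity correction), and selects the best-fitting ratio
#' as the one with the largest p-value.
#'
#' @param n_dominant,n_recessive Observed phenotype counts (not both zero).
#' @param ratios Candidate ratios, as strings `"a:b"` (a, b > 0). The
#'   default covers single-gene dominance and the common two-gene models.
#' @return A list with `fits` — a tibble of `ratio`, `expected_dominant`,
#'   `expected_recessive`, `chisq`, `df`, `p_value` — and `best_ratio`, the
#'   ratio string maximizing the p-value.
#' @export
segregation_test <- function(n_dominant, n_recessive,
                             ratios = c("3:1", "1:1", "13:3", "15:1")) {
  stopifnot(n_dominant >= 0, n_recessive >= 0, n_dominant + n_recessive > 0)
  parsed <- lapply(strsplit(ratios, ":", fixed = TRUE), as.numeric)
  bad <- vapply(parsed, function(r) {
    length(r) != 2 || anyNA(r) || any(r <= 0)
  }, logical(1))
  if (any(bad)) {
    abort(paste0("invalid ratio: '", ratios[bad][1], "'"))
  }
  N <- n_dominant + n_recessive
  rows <- lapply(seq_along(ratios), function(i) {
    a <- parsed[[i]][1]
    b <- parsed[[i]][2]
    exp_dom <- N * a / (a + b)
    exp_rec <- N * b / (a + b)
    if (exp_dom == 0 || exp_rec == 0) {
      warn(paste0("ratio ", ratios[i], " gives a zero expected count; skipped"))
      return(NULL)
    }
    chisq <- (n_dominant - exp_dom)^2 / exp_dom +
      (n_recessive - exp_rec)^2 / exp_rec
    tibble(
      ratio = ratios[i],
      expected_dominant = exp_dom, expected_recessive = exp_rec,
      chisq = chisq, df = 1L,
      p_value = pchisq(chisq, df = 1, lower.tail = FALSE)
    )
  })
  fits <- bind_rows(rows)
  if (nrow(fits) == 0) {
    abort("no testable ratio")
  }
  list(fits = fits, best_ratio = fits$ratio[which.max(fits$p_value)])
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes per-sample `dCt = Ct_target - Ct_reference` (technical
#' replicates are averaged first), `ddCt = dCt - dCt_calibrator` and the
#' relative expression `2^-ddCt`, normalized to a reference gene (e.g.
#' BrActin, Bra028615) and a calibrator sample or group. Group means, SDs
#' and Tukey HSD compact-letter groupings (alpha = 0.05) are reported per
#' target gene.
#'
#' @param ct A tibble with columns `sample`, `group`, `gene`, `ct`.
#' @param reference_gene Name of the internal-control gene in `ct`.
#' @param calibrator Sample name (or group name) whose dCt anchors ddCt;
#'   for a group, its mean dCt is used. Required — never defaulted.
#' @param alpha Significance level for the Tukey grouping letters.
#' @param letters_on Scale on which Tukey HSD runs: untransformed relative
#'   expression (`"linear"`, default) or `"log2"`.
#' @return A list with `samples` (tibble `gene`, `sample`, `group`, `dct`,
#'   `ddct`, `rel_expr`) and `groups` (tibble `gene`, `group`, `mean_expr`,
#'   `sd_expr`, `n`, `letters`).
#' @export
relative_expression <- function(ct, reference_gene, calibrator,
                                alpha = 0.05,
                                letters_on = c("linear", "log2")) {
  letters_on <- match.arg(letters_on)
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(ct))) {
    abort("ct table must have columns sample, group, gene, ct")
  }
  if (!reference_gene %in% ct$gene) {
    abort(paste0("reference gene '", reference_gene, "' not in ct table"))
  }
  # average technical replicates per (sample, gene)
  avg <- summarise(
    group_by(ct, .data$sample, .data$group, .data$gene),
    ct = mean(.data$ct), .groups = "drop"
  )
  ref <- avg[avg$gene == reference_gene, c("sample", "ct")]
  names(ref)[2] <- "ct_ref"
  targets <- avg[avg$gene != reference_gene, , drop = FALSE]
  merged <- left_join(targets, ref, by = "sample")
  no_ref <- is.na(merged$ct_ref)
  if (any(no_ref)) {
    warn(paste0(
      "sample(s) without reference-gene Ct excluded: ",
      paste(unique(merged$sample[no_ref]), collapse = ", ")
    ))
    merged <- merged[!no_ref, , drop = FALSE]
  }
  merged$dct <- merged$ct - merged$ct_ref

  is_cal_sample <- merged$sample == calibrator
  is_cal_group <- merged$group == calibrator
  if (!any(is_cal_sample) && !any(is_cal_group)) {
    abort(paste0("calibrator '", calibrator, "' matches no sample or group"))
  }

  per_gene <- lapply(split(merged, merged$gene), function(d) {
    cal <- if (any(d$sample == calibrator)) {
      d$dct[d$sample == calibrator]
    } else {
      d$dct[d$group == calibrator]
    }
    if (length(cal) == 0) {
      abort(paste0(
        "calibrator '", calibrator, "' has no dCt for gene '", d$gene[1], "'"
      ))
    }
    d$ddct <- d$dct - mean(cal)
    d$rel_expr <- 2^(-d$ddct)
    d
  })
  samples <- bind_rows(per_gene)

  groups <- bind_rows(lapply(split(samples, samples$gene), function(d) {
    y <- if (letters_on == "log2") log2(d$rel_expr) else d$rel_expr
    letters <- tukey_letters(y, d$group, alpha = alpha)
    g <- summarise(
      group_by(d, .data$group),
      mean_expr = mean(.data$rel_expr), sd_expr = sd(.data$rel_expr),
      n = dplyr::n(), .groups = "drop"
    )
    g$gene <- d$gene[1]
    g$letters <- letters[g$group]
    g[, c("gene", "group", "mean_expr", "sd_expr", "n", "letters")]
  }))

  list(
    samples = samples[, c(
      "gene", "sample", "group", "dct", "ddct", "rel_expr"
    )],
    groups = groups
  )
}

#' Tukey HSD compact letter display
#'
#' All-pairs Tukey honestly-significant-difference comparisons on a one-way
#' layout, summarized as grouping letters (groups sharing a letter are not
#' significantly different; `"a"` attaches to the largest mean). Implements
#' the insert-and-absorb letter algorithm on the `TukeyHSD` p-values. With
#' zero residual variance (e.g. all observations identical within groups)
#' pairs are separated exactly when their means differ.
#'
#' @param y Numeric response values.
#' @param group Group labels (coerced to factor).
#' @param alpha Significance level.
#' @return Named character vector of letters, one per group level.
#' @export
tukey_letters <- function(y, group, alpha = 0.05) {
  group <- factor(group)
  lev <- levels(group)
  k <- length(lev)
  means <- tapply(y, group, mean)
  if (k == 1) {
    return(setNames("a", lev))
  }

  # pairwise significance matrix
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  resid_var <- sum(tapply(y, group, function(v) {
    sum((v - mean(v))^2)
  })) / max(1, length(y) - k)
  if (!is.finite(resid_var) || resid_var < .Machine$double.eps^0.75) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) >
          sqrt(.Machine$double.eps)
      }
    }
  } else {
    tk <- TukeyHSD(aov(y ~ group), conf.level = 1 - alpha)$group
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (r in seq_len(nrow(tk))) {
      i <- pairs[[r]][1]
      j <- pairs[[r]][2]
      s <- is.finite(tk[r, "p adj"]) && tk[r, "p adj"] < alpha
      sig[i, j] <- sig[j, i] <- s
    }
  }

  # insert-and-absorb on groups ordered by decreasing mean
  ord <- names(sort(means, decreasing = TRUE))
  cols <- list(ord)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- ord[i]
      b <- ord[j]
      if (!sig[a, b]) next
      both <- vapply(cols, function(cl) a %in% cl && b %in% cl, logical(1))
      if (!any(both)) next
      new_cols <- list()
      for (ci in seq_along(cols)) {
        if (!both[ci]) {
          new_cols <- c(new_cols, cols[ci])
        } else {
          new_cols <- c(new_cols, list(
            setdiff(cols[[ci]], a), setdiff(cols[[ci]], b)
          ))
        }
      }
      # absorb: drop columns that are subsets of another
      keep <- rep(TRUE, length(new_cols))
      for (ci in seq_along(new_cols)) {
        for (cj in seq_along(new_cols)) {
          if (ci != cj && keep[cj] &&
            all(new_cols[[ci]] %in% new_cols[[cj]]) &&
            (length(new_cols[[ci]]) < length(new_cols[[cj]]) || ci > cj)) {
            keep[ci] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }

  # order columns by the best (largest-mean) member, assign letters
  first_rank <- vapply(cols, function(cl) min(match(cl, ord)), numeric(1))
  cols <- cols[order(first_rank)]
  out <- setNames(rep("", k), lev)
  for (ci in seq_along(cols)) {
    for (g in cols[[ci]]) {
      out[g] <- paste0(out[g], letters[ci])
    }
  }
  out
}
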