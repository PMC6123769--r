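#' Selection configuration
#'
#' Tuning knobs of the iterative isomorphism selection.
#'
#' @param cc_threshold Minimum CC_dataset in the decision shell; a dataset at
#'   exactly the threshold is kept. Either a fixed number in (-1, 1) or
#'   "auto": each iteration rejects robust outliers below
#'   `median(CC) - 3 * mad(CC)` — the label-free analog of choosing the
#'   cutoff case by case, which adapts to the ensemble's noise level.
#' @param decision_shell Shell index whose CC drives the keep/reject decision,
#'   or "overall". Default 2: the second-lowest-resolution shell, which is
#'   populated enough to be stable but still dominated by isomorphism rather
#'   than noise.
#' @param n_lowres_shells_presort Number of lowest-resolution shells averaged
#'   for the R_meas presort.
#' @param statistic Decision statistic: "cc" (raw Pearson CC_dataset) or
#'   "cc_norm" (CC divided by the attenuation expected from the paired
#'   sigmas). The normalized form scores weak-but-isomorphous data near 1,
#'   separating low CC caused by noise from low CC caused by
#'   non-isomorphism.
#' @param isa_min Minimum per-dataset ISa; NULL disables the prefilter.
#' @param max_iter Maximum selection iterations.
#' @param min_kept Guard: selection never returns fewer surviving datasets.
#' @param seed Seed for stochastic sub-steps (CC1/2 half splits).
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(cc_threshold = 0.5, decision_shell = 2,
                             statistic = c("cc", "cc_norm"),
                             n_lowres_shells_presort = 3, isa_min = NULL,
                             max_iter = 10, min_kept = 2, seed = 0) {
  statistic <- match.arg(statistic)
  if (identical(cc_threshold, "auto")) {
    # adaptive per-iteration outlier cut
  } else if (!(is.numeric(cc_threshold) && cc_threshold > -1 && cc_threshold < 1)) {
    stop("cc_threshold must be in (-1, 1) or \"auto\"")
  }
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (min_kept < 1) stop("min_kept must be >= 1")
  if (!identical(decision_shell, "overall")) {
    decision_shell <- as.integer(decision_shell)
    if (decision_shell < 1) stop("decision_shell must be >= 1 or 'overall'")
  }
  structure(list(cc_threshold = cc_threshold, decision_shell = decision_shell,
                 statistic = statistic,
                 n_lowres_shells_presort = as.integer(n_lowres_shells_presort),
                 isa_min = isa_min, max_iter = as.integer(max_iter),
                 min_kept = as.integer(min_kept), seed = as.integer(seed)),
            class = "selection_config")
}

#' Presort datasets by low-resolution internal R_meas
#'
#' Each dataset's internal R_meas is computed per shell from its own
#' symmetry-equivalent observations (Friedel mates counted as equivalents)
#' and averaged over the `n_low` lowest-resolution shells. Datasets are
#' ordered ascending by that average — cleanest first, so the best data seed
#' the merging reference. Datasets with fewer than 20 multiplicity-2 groups
#' in those shells cannot be ranked reliably and are appended at the end,
#' flagged.
#'
#' @param datasets List of [xtal_dataset()].
#' @param shells A [make_shells()] scheme covering the data.
#' @param n_low Number of low-resolution shells to average.
#' @return data.frame (one row per dataset, in sort order) with columns
#'   `id`, `rmeas_lowres`, `n_groups`, `low_multiplicity`.
#' @export
presort_by_lowres_rmeas <- function(datasets, shells, n_low = 3) {
  stopifnot(is_shell_scheme(shells))
  rows <- lapply(datasets, function(ds) {
    pool <- pool_observations(list(ds), list(scale_model(1, 0)), anomalous = FALSE)
    sel <- shell_index(shells, pool$d) <= n_low
    pool <- pool[sel, , drop = FALSE]
    if (nrow(pool) == 0)
      return(data.frame(id = ds$id, rmeas_lowres = NA_real_, n_groups = 0L,
                        low_multiplicity = TRUE))
    grp <- factor(pool$key)
    n <- as.vector(rowsum(rep(1, nrow(pool)), grp))
    si <- as.vector(rowsum(pool$i, grp))
    mean_i <- si / n
    absdev <- as.vector(rowsum(abs(pool$i - mean_i[grp]), grp))
    ok <- n >= 2
    rmeas <- if (any(ok) && sum(si[ok]) != 0)
      sum(sqrt(n[ok] / (n[ok] - 1)) * absdev[ok]) / sum(si[ok])
    else NA_real_
    data.frame(id = ds$id, rmeas_lowres = rmeas, n_groups = sum(ok),
               low_multiplicity = sum(ok) < 20 || !is.finite(rmeas))
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$low_multiplicity, tab$rmeas_lowres, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Correlation of one dataset against a merged reference, per shell
#'
#' The dataset's observations are merged per unique key, paired with the
#' reference entries, and the Pearson correlation of intensities is returned
#' for each resolution shell and overall. Shells with fewer than 5 pairs are
#' undefined (NA). The reference must not contain the dataset's own
#' observations (leave-one-out) for an unbiased value.
#'
#' @param dataset An [xtal_dataset()].
#' @param reference A [merged_set()] excluding this dataset.
#' @param shells A [make_shells()] scheme.
#' @param scale A [scale_model()] for the dataset (the statistic is
#'   scale-invariant per shell; scaling matters only across shells).
#' @return data.frame with columns `shell` ("1"... and "overall"), `n_pairs`,
#'   `cc` and `cc_norm` (noise-attenuation-corrected CC).
#' @export
cc_dataset <- function(dataset, reference, shells, scale = scale_model(1, 0)) {
  stopifnot(is_xtal_dataset(dataset), is_merged_set(reference))
  own <- merge_sums(pool_observations(list(dataset), list(scale),
                                      anomalous = reference$anomalous))
  ref_key <- encode_key(reference$entries)
  m <- match(own$key, ref_key)
  ok <- !is.na(m)
  own_i <- (own$swi / own$sw)[ok]
  ref_i <- reference$entries$i[m[ok]]
  d <- d_spacing(dataset$cell, as.matrix(decode_key(own$key[ok])[c("h", "k", "l")]))
  cc_by_shell(own_i, ref_i, shell_index(shells, d), shells$n_shells,
              sx = 1 / sqrt(own$sw[ok]), sy = reference$entries$sigma[m[ok]])
}

cc_by_shell <- function(x, y, sh, n_shells, min_pairs = 5,
                        sx = NULL, sy = NULL) {
  # attenuation a Pearson CC suffers from measurement noise: the signal
  # variance is the observed variance minus the mean squared sigma
  atten <- function(v, s) {
    tot <- stats::var(v)
    if (!is.finite(tot) || tot <= 0) return(NA_real_)
    sqrt(max(tot - mean(s^2), 0.05 * tot) / tot)
  }
  one <- function(sel) {
    n <- sum(sel)
    cc <- if (n >= min_pairs)
      suppressWarnings(stats::cor(x[sel], y[sel])) else NA_real_
    ccn <- if (!is.null(sx) && !is.na(cc))
      cc / (atten(x[sel], sx[sel]) * atten(y[sel], sy[sel]))
    else NA_real_
    c(n_pairs = n, cc = cc, cc_norm = min(ccn, 1.5))
  }
  rows <- t(vapply(seq_len(n_shells), function(s) one(sh == s), numeric(3)))
  overall <- one(rep(TRUE, length(x)))
  out <- data.frame(shell = c(as.character(seq_len(n_shells)), "overall"),
                    rbind(rows, overall))
  if (is.null(sx)) out$cc_norm <- NULL
  rownames(out) <- NULL
  out
}

subtract_sums <- function(a, b) {
  m <- match(b$key, a$key)
  hit <- !is.na(m)
  idx <- m[hit]
  a$sw[idx] <- a$sw[idx] - b$sw[hit]
  a$swi[idx] <- a$swi[idx] - b$swi[hit]
  a$n[idx] <- a$n[idx] - b$n[hit]
  a[a$n > 0.5, , drop = FALSE]
}

#' Iterative CC_dataset selection of isomorphous datasets
#'
#' The core selection pipeline: (1) optional ISa prefilter; (2) presort by
#' averaged low-resolution internal R_meas; (3) sequential scale-and-merge of
#' the survivors into a preliminary reference; (4) leave-one-out CC_dataset
#' for every candidate (previously CC-rejected datasets are re-evaluated and
#' may re-enter; ISa-rejected and unscalable ones never do); (5) rejection of
#' candidates below `cc_threshold` in the decision shell; (6) re-merge and
#' repeat until membership is stable or `max_iter`. If a step would leave
#' fewer than `min_kept` survivors, the last valid membership is returned
#' with a warning flag.
#'
#' Selection statistics (CC, scaling) are computed on Friedel-merged
#' intensities; `anomalous` controls only the final merged output.
#'
#' @param datasets List of [xtal_dataset()].
#' @param config A [selection_config()].
#' @param shells A [make_shells()] scheme; NULL derives 10 equal-volume
#'   shells from the pooled resolution range.
#' @param anomalous Produce the final merged set Friedel-separated?
#' @return Object of class `selection_result`: `kept` (ids), `rejected`
#'   (named character vector of reasons: "isa", "cc", "unscalable"), `trace`
#'   (per-iteration CC table), `selection_rate`, `merged` (final
#'   [merged_set()]), `scales`, `shells`, `iterations`, `converged`,
#'   `min_kept_triggered`.
#' @export
select_datasets <- function(datasets, config = selection_config(),
                            shells = NULL, anomalous = FALSE) {
  ids <- vapply(datasets, function(d) d$id, "")
  if (anyDuplicated(ids)) stop("duplicate dataset ids")
  names(datasets) <- ids
  n_input <- length(datasets)
  if (n_input < config$min_kept) stop("fewer datasets than min_kept")
  if (is.null(shells)) shells <- default_shells(datasets)
  rejected <- character(0)

  # (1) ISa prefilter: drop datasets whose own error model is confidently bad;
  # datasets where ISa cannot be estimated pass through unfiltered
  if (!is.null(config$isa_min)) {
    isa <- vapply(datasets, function(ds) {
      f <- tryCatch(fit_error_model(list(ds)), error = function(e) NULL)
      if (is.null(f) || !f$ok) NA_real_ else f$isa
    }, 0)
    drop <- !is.na(isa) & isa < config$isa_min
    rejected <- c(rejected, stats::setNames(rep("isa", sum(drop)), ids[drop]))
    datasets <- datasets[!drop]
    if (length(datasets) < config$min_kept)
      stop("ISa prefilter left fewer than min_kept datasets")
  }

  # (2) presort, (3) preliminary scale + merge
  presort <- presort_by_lowres_rmeas(datasets, shells,
                                     config$n_lowres_shells_presort)
  datasets <- datasets[presort$id]
  sm <- scale_and_merge(datasets, anomalous = FALSE)
  rejected <- c(rejected,
                stats::setNames(rep("unscalable", length(sm$unscalable)),
                                sm$unscalable))
  cand_ids <- setdiff(names(datasets), sm$unscalable)
  if (length(cand_ids) < config$min_kept) stop("fewer scalable datasets than min_kept")
  cand <- datasets[cand_ids]
  scales <- sm$scales[cand_ids]
  cell <- cand[[1]]$cell

  # per-candidate merged-own sums and shell labels, computed once
  own <- lapply(cand_ids, function(id)
    merge_sums(pool_observations(cand[id], scales[id], anomalous = FALSE)))
  names(own) <- cand_ids
  own_shell <- lapply(own, function(o) {
    d <- d_spacing(cell, as.matrix(decode_key(o$key)[c("h", "k", "l")]))
    shell_index(shells, d)
  })

  col <- config$statistic
  decision_cc <- function(tab) {
    v <- if (identical(config$decision_shell, "overall")) NA_real_
         else tab[[col]][tab$shell == as.character(config$decision_shell)]
    if (length(v) == 0 || is.na(v)) v <- tab[[col]][tab$shell == "overall"]
    v
  }

  members <- cand_ids
  trace <- list()
  min_kept_triggered <- FALSE
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    total <- Reduce(combine_sums, own[members])
    cc_val <- stats::setNames(rep(NA_real_, length(cand_ids)), cand_ids)
    for (id in cand_ids) {
      ref <- if (id %in% members) subtract_sums(total, own[[id]]) else total
      m <- match(own[[id]]$key, ref$key)
      ok <- !is.na(m) & ref$n[ifelse(is.na(m), 1L, m)] >= 1
      tab <- cc_by_shell((own[[id]]$swi / own[[id]]$sw)[ok],
                         (ref$swi / ref$sw)[m[ok]],
                         own_shell[[id]][ok], shells$n_shells,
                         sx = 1 / sqrt(own[[id]]$sw[ok]),
                         sy = 1 / sqrt(ref$sw[m[ok]]))
      cc_val[id] <- decision_cc(tab)
    }
    thr <- if (identical(config$cc_threshold, "auto"))
      stats::median(cc_val, na.rm = TRUE) -
        3 * max(stats::mad(cc_val, na.rm = TRUE), 0.01)
    else config$cc_threshold
    keep <- !is.na(cc_val) & cc_val >= thr
    new_members <- cand_ids[keep]
    trace[[iter]] <- data.frame(iter = iter, id = cand_ids, cc = unname(cc_val),
                                threshold = thr,
                                decision = ifelse(keep, "keep", "reject"))
    if (length(new_members) < config$min_kept) {
      min_kept_triggered <- TRUE
      warning("CC selection would leave fewer than min_kept datasets; ",
              "returning last valid membership")
      break
    }
    if (setequal(new_members, members)) {
      members <- new_members
      converged <- TRUE
      break
    }
    members <- new_members
  }

  rejected <- c(rejected,
                stats::setNames(rep("cc", sum(!cand_ids %in% members)),
                                setdiff(cand_ids, members)))
  merged <- merge_datasets(cand[members], scales[members], anomalous = anomalous)
  structure(list(
    kept = members, rejected = rejected,
    trace = do.call(rbind, trace),
    selection_rate = length(members) / n_input,
    merged = merged, scales = scales[members], shells = shells,
    iterations = iter, converged = converged,
    min_kept_triggered = min_kept_triggered,
    config = config, n_input = n_input), class = "selection_result")
}

default_shells <- function(datasets, n_shells = 10) {
  d <- unlist(lapply(datasets, dataset_d))
  make_shells(max(d) * (1 + 1e-9), min(d) * (1 - 1e-9), n_shells, "equal_volume")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Dataset selection: kept %d of %d (selection rate %.0f%%), %d iteration(s)%s%s\n",
              length(x$kept), x$n_input, 100 * x$selection_rate, x$iterations,
              if (x$converged) ", converged" else "",
              if (x$min_kept_triggered) " [min_kept guard]" else ""))
  if (length(x$rejected)) {
    tab <- table(x$rejected)
    cat("Rejected:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.selection_result <- function(object, ...) {
  print(object)
  last <- object$trace[object$trace$iter == max(object$trace$iter), ]
  cat(sprintf("Final-iteration CC_dataset: median %.3f, range %.3f to %.3f\n",
              stats::median(last$cc, na.rm = TRUE),
              min(last$cc, na.rm = TRUE), max(last$cc, na.rm = TRUE)))
  print(object$merged)
  invisible(object)
}

#' Write a selection report as JSON
#'
#' Serialises a [select_datasets()] result (config, counts, kept/rejected
#' ids, per-iteration mean CC, final shell statistics) to a JSON file.
#'
#' @param result A `selection_result`.
#' @param path Output path.
#' @param final_stats Optional [shell_statistics()] table for the kept
#'   datasets; NULL omits the section.
#' @return The path, invisibly.
#' @export
write_selection_report <- function(result, path, final_stats = NULL) {
  stopifnot(inherits(result, "selection_result"))
  tr <- result$trace
  iters <- lapply(split(tr, tr$iter), function(x) list(
    iter = x$iter[1],
    rejected_ids = x$id[x$decision == "reject"],
    mean_cc = mean(x$cc, na.rm = TRUE)))
  report <- list(
    config = unclass(result$config),
    n_input = result$n_input,
    n_processed = result$n_input,
    kept = result$kept,
    rejected = as.list(result$rejected),
    selection_rate = result$selection_rate,
    iterations = unname(iters),
    converged = result$converged,
    min_kept_guard = result$min_kept_triggered)
  if (!is.null(final_stats)) report$final_stats <- as.data.frame(final_stats)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
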