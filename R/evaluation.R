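#' Evaluate all clip pairs with one method
#'
#' Prepares every clip once (normalization, smoothing, conditional cropping,
#' segmentation, address centering), then scores every unordered clip pair —
#' no self-pairs, each pair once — with the chosen method. Clips that fail to
#' load or segment are excluded with a logged reason (available in the
#' `"failures"` attribute) rather than failing the whole batch, mirroring
#' practice-range data quality.
#'
#' @param clips a `clip_manifest` from [read_manifest()], a list of
#'   [pose_sequence()] objects, or a list of `synthetic_clip`s.
#' @param method method id (see [similarity_config()]); default `"dmsm"`.
#' @param cfg a [similarity_config()].
#' @return A `data.frame` of class `eval_table` with one row per pair:
#'   clip/player ids, method, `overall_similarity`, `overall_DS`, per-phase
#'   `DS_<phase>` columns (populated for DMSM), and
#'   `pair_class` in `{same_player, cross_player}`.
#' @export
pairwise_evaluation <- function(clips, method = "dmsm",
                                cfg = similarity_config()) {
  seqs <- load_clip_list(clips)
  if (length(seqs) < 2L)
    stop("need at least 2 clips", call. = FALSE)
  prepared <- list()
  failures <- data.frame(clip_id = character(0), reason = character(0))
  for (s in seqs) {
    p <- tryCatch(as_prepared(s, cfg), error = function(e) e)
    if (inherits(p, "error")) {
      failures <- rbind(failures, data.frame(clip_id = s$clip_id,
                                             reason = conditionMessage(p)))
    } else {
      prepared[[length(prepared) + 1L]] <- p
    }
  }
  if (nrow(failures))
    warning("excluded ", nrow(failures), " clip(s): ",
            paste(failures$clip_id, collapse = ", "), call. = FALSE)
  n <- length(prepared)
  if (n < 2L) stop("fewer than 2 clips survived preparation", call. = FALSE)
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    a <- prepared[[i]]; b <- prepared[[j]]
    res <- compare_swings(a, b, method, cfg)
    ph <- rep(NA_real_, 7)
    if (!is.null(res$report))
      ph <- vapply(res$report$phase_scores, `[[`, numeric(1), "weighted_DS")
    row <- data.frame(clip_a = a$seq$clip_id, clip_b = b$seq$clip_id,
                      player_a = a$seq$player_id, player_b = b$seq$player_id,
                      method = method,
                      overall_similarity = res$similarity,
                      overall_DS = res$DS)
    for (k in 1:7) row[[paste0("DS_", phase_names[k])]] <- ph[k]
    row$pair_class <- if (a$seq$player_id == b$seq$player_id)
      "same_player" else "cross_player"
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  class(out) <- c("eval_table", "data.frame")
  out
}

load_clip_list <- function(clips) {
  if (inherits(clips, "clip_manifest")) {
    lapply(seq_len(nrow(clips)), function(i)
      read_pose_sequence(clips$path[i], format = "csv",
                         clip_id = clips$clip_id[i],
                         player_id = clips$player_id[i],
                         handedness = clips$handedness[i],
                         fps = clips$fps[i]))
  } else if (is.list(clips)) {
    lapply(clips, function(cl) {
      if (inherits(cl, "synthetic_clip")) cl$sequence
      else if (inherits(cl, "pose_sequence") ||
                 inherits(cl, "prepared_swing")) cl
      else stop("unsupported clip object of class ", class(cl)[1],
                call. = FALSE)
    })
  } else stop("clips must be a manifest or a list of clips", call. = FALSE)
}

#' Same-player vs cross-player separation statistics
#'
#' Summarizes how well a dissimilarity separates repeat swings of one player
#' from swings of different players: class means on the DS scale, their
#' difference (`separation = mean_cross - mean_same`), a Welch two-sample
#' t-test (the two classes are not paired observations), Shapiro-Wilk
#' normality checks per class, Cohen's d with pooled standard deviation, and
#' a seeded percentile-bootstrap confidence interval for the separation.
#'
#' @param table an `eval_table` from [pairwise_evaluation()].
#' @param n_bootstrap bootstrap replicates (default 2000, >= 100).
#' @param seed integer seed for the bootstrap resampling.
#' @param conf confidence level (default 0.95).
#' @return A `separation_stats` list.
#' @export
separation_statistics <- function(table, n_bootstrap = 2000L, seed = 1L,
                                  conf = 0.95) {
  if (n_bootstrap < 100L) stop("n_bootstrap must be >= 100", call. = FALSE)
  same <- table$overall_DS[table$pair_class == "same_player"]
  cross <- table$overall_DS[table$pair_class == "cross_player"]
  if (!length(same) || !length(cross))
    stop("separation needs at least one same-player and one cross-player pair",
         call. = FALSE)
  shapiro_of <- function(v, label) {
    if (length(v) < 3L) {
      warning("fewer than 3 ", label, " values; normality test skipped",
              call. = FALSE)
      return(NA_real_)
    }
    if (stats::sd(v) < 1e-15) return(NA_real_)
    stats::shapiro.test(v[seq_len(min(length(v), 5000L))])$p.value
  }
  tt <- if (length(same) > 1L && length(cross) > 1L &&
              (stats::sd(same) > 1e-15 || stats::sd(cross) > 1e-15))
    stats::t.test(cross, same) else NULL
  n1 <- length(cross); n2 <- length(same)
  sp <- sqrt(((n1 - 1) * stats::var(cross) + (n2 - 1) * stats::var(same)) /
               max(n1 + n2 - 2, 1))
  d <- if (is.finite(sp) && sp > 0) (mean(cross) - mean(same)) / sp else NA_real_
  boot <- with_local_seed(seed, {
    vapply(seq_len(n_bootstrap), function(i)
      mean(sample(cross, n1, replace = TRUE)) -
        mean(sample(same, n2, replace = TRUE)), numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
  structure(list(
    n_same = n2, n_cross = n1,
    mean_same = mean(same), mean_cross = mean(cross),
    separation = mean(cross) - mean(same),
    t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    p_value = if (is.null(tt)) NA_real_ else tt$p.value,
    shapiro_p_same = shapiro_of(same, "same-player"),
    shapiro_p_cross = shapiro_of(cross, "cross-player"),
    cohens_d = d,
    bootstrap_ci_95 = ci,
    n_bootstrap = n_bootstrap, seed = seed),
    class = "separation_stats")
}

#' @export
print.separation_stats <- function(x, ...) {
  cat("<separation_stats>\n")
  cat(sprintf("  mean DS same %.4f (n=%d) | cross %.4f (n=%d)\n",
              x$mean_same, x$n_same, x$mean_cross, x$n_cross))
  cat(sprintf("  separation %.4f  [%.4f, %.4f] (bootstrap 95%%)\n",
              x$separation, x$bootstrap_ci_95[1], x$bootstrap_ci_95[2]))
  cat(sprintf("  Welch t = %.3f, p = %.3g | Cohen's d = %.3f\n",
              x$t_statistic, x$p_value, x$cohens_d))
  cat(sprintf("  Shapiro-Wilk p: same %.3g, cross %.3g\n",
              x$shapiro_p_same, x$shapiro_p_cross))
  invisible(x)
}

#' Benchmark several similarity methods on the same clips
#'
#' Runs [pairwise_evaluation()] for every method on identical pair lists,
#' computes per-method separation statistics, and tests each method against
#' the first with a *paired* t-test on the per-pair similarities (pairing is
#' well defined here because the clip pairs are identical across methods).
#'
#' @param clips as in [pairwise_evaluation()].
#' @param methods character vector of method ids (first = reference).
#' @param cfg a [similarity_config()].
#' @param n_bootstrap,seed passed to [separation_statistics()].
#' @return A `method_comparison` list: `summary` (one row per method with
#'   mean +/- sd similarity, separation, and p vs the reference method),
#'   `stats` (per-method `separation_stats` or `NULL`), and `tables`
#'   (per-method `eval_table`s).
#' @export
method_comparison <- function(clips, methods, cfg = similarity_config(),
                              n_bootstrap = 2000L, seed = 1L) {
  if (!length(methods)) stop("methods must be non-empty", call. = FALSE)
  seqs <- load_clip_list(clips)
  prepared <- lapply(seqs, as_prepared, cfg = cfg)
  tables <- lapply(methods, function(m)
    pairwise_evaluation(prepared, method = m, cfg = cfg))
  names(tables) <- make.unique(methods)
  stats_list <- lapply(tables, function(tb)
    tryCatch(separation_statistics(tb, n_bootstrap, seed),
             error = function(e) NULL))
  ref_sim <- tables[[1]]$overall_similarity
  summary <- do.call(rbind, lapply(seq_along(methods), function(k) {
    tb <- tables[[k]]
    diffs <- tb$overall_similarity - ref_sim
    p <- if (k == 1L) NA_real_
    else if (stats::sd(diffs) < 1e-14) if (all(abs(diffs) < 1e-14)) 1 else NA_real_
    else stats::t.test(tb$overall_similarity, ref_sim, paired = TRUE)$p.value
    st <- stats_list[[k]]
    data.frame(method = methods[k],
               mean_similarity = mean(tb$overall_similarity),
               sd_similarity = stats::sd(tb$overall_similarity),
               mean_DS = mean(tb$overall_DS),
               separation = if (is.null(st)) NA_real_ else st$separation,
               p_value = if (is.null(st)) NA_real_ else st$p_value,
               cohens_d = if (is.null(st)) NA_real_ else st$cohens_d,
               p_vs_reference = p,
               mean_paired_diff = if (k == 1L) 0 else mean(diffs))
  }))
  structure(list(summary = summary, stats = stats_list, tables = tables),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  df <- x$summary
  df$mean_similarity <- sprintf("%.3f +/- %.3f", df$mean_similarity,
                                df$sd_similarity)
  print(df[, c("method", "mean_similarity", "separation", "p_value",
               "p_vs_reference")], row.names = FALSE)
  invisible(x)
}
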