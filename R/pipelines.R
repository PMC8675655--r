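#' Results container for a cohort analysis
#'
#' Long-format per-disc quantification records (one row per disc x metric x
#' scope) plus cohort-level test rows and a structured per-disc log (chosen
#' thresholds, counts, warnings) so threshold drift between discs is
#' auditable.
#'
#' @param quant data frame with columns `disc_id`, `metric`, `scope`,
#'   `value`, `units`, `flag`.
#' @param tests data frame with columns `test_name`, `metric`, `scope_a`,
#'   `scope_b`, `statistic`, `p_value`, `n`, `method`, `note`.
#' @param log character vector of log lines.
#' @return a `results_table`.
#' @export
results_table <- function(quant = empty_quant(), tests = empty_tests(),
                          log = character()) {
  structure(list(quant = quant, tests = tests, log = log),
            class = "results_table")
}

empty_quant <- function() {
  data.frame(disc_id = character(), metric = character(), scope = character(),
             value = numeric(), units = character(), flag = character())
}

empty_tests <- function() {
  data.frame(test_name = character(), metric = character(),
             scope_a = character(), scope_b = character(),
             statistic = numeric(), p_value = numeric(), n = character(),
             method = character(), note = character())
}

quant_row <- function(disc_id, metric, scope, value, units, flag = "") {
  data.frame(disc_id = disc_id, metric = metric, scope = scope,
             value = value, units = units, flag = flag)
}

test_row <- function(res, metric, scope_a, scope_b, note = "") {
  if (is.null(res))
    return(data.frame(test_name = "wilcoxon_signed_rank", metric = metric,
                      scope_a = scope_a, scope_b = scope_b,
                      statistic = NA_real_, p_value = NA_real_, n = "0",
                      method = "none", note = note))
  data.frame(test_name = res$test_name, metric = metric, scope_a = scope_a,
             scope_b = scope_b, statistic = res$statistic,
             p_value = res$p_value, n = paste(res$n, collapse = "/"),
             method = res$method,
             note = if (is.null(res$note)) note else
               paste(c(note, res$note), collapse = "; "))
}

#' @export
print.results_table <- function(x, ...) {
  cat(sprintf("<results_table> %d quantification row(s), %d test row(s)\n",
              nrow(x$quant), nrow(x$tests)))
  if (nrow(x$tests)) print(x$tests, row.names = FALSE, digits = 4)
  invisible(x)
}

# normalize pipeline input: a list of discs, each list(stack, pouch, ...);
# simulate_* output (list(stack, truth)) is accepted directly, the pouch
# ROI being taken from the ground truth
normalize_discs <- function(discs) {
  lapply(seq_along(discs), function(i) {
    d <- discs[[i]]
    if (!is.null(d$truth) && is.null(d$pouch)) d$pouch <- d$truth$pouch_mask
    if (is.null(d$stack) || is.null(d$pouch))
      stop("disc ", i, " must provide 'stack' and 'pouch' (or a ground truth)")
    if (is.null(d$id)) d$id <- sprintf("disc_%02d", i)
    d
  })
}

#' Run the mosaic (clone competition) pipeline on a cohort
#'
#' Per disc: segment GFP patches within the pouch, decompose them into
#' border and center territories, segment death-marker voxels, and record
#' pouch coverage plus per-territory death densities. Cohort level: a paired
#' two-sided Wilcoxon signed-rank test of border vs center death density
#' over discs with both territories non-empty (discs with an empty center
#' are flagged and excluded from the pairing).
#'
#' @param discs list of discs; each is `list(stack, pouch, id)` or the
#'   `list(stack, truth)` pairs produced by [simulate_cohort()].
#' @param config list of options: `cell_diameter` (um or `"auto"`),
#'   `n_cell_diameters` (default 2), `min_volume` (um^3 or `NULL` for one
#'   nuclear volume), `smooth_sigma`, `death_smooth_sigma`, `threshold` /
#'   `death_threshold` overrides.
#' @return a [results_table].
#' @export
run_mosaic_pipeline <- function(discs, config = list()) {
  discs <- normalize_discs(discs)
  ncd <- config$n_cell_diameters %||% 2
  quant <- list()
  logs <- character()
  border <- center <- rep(NA_real_, length(discs))
  for (i in seq_along(discs)) {
    d <- discs[[i]]
    cd <- config$cell_diameter %||% "auto"
    if (identical(cd, "auto")) cd <- estimate_cell_diameter(d$stack)
    min_vol <- config$min_volume %||% ((4 / 3) * pi * (cd / 2)^3)
    patches <- segment_patches(d$stack, d$pouch, min_volume = min_vol,
                               smooth_sigma = config$smooth_sigma %||% 1,
                               threshold = config$threshold)
    cov <- pouch_coverage(patches, d$pouch)
    quant[[length(quant) + 1L]] <-
      quant_row(d$id, "coverage_pct", "pouch", cov, "percent")
    if (!any(patches$labels > 0L)) {
      logs <- c(logs, sprintf("%s: no patches segmented; skipped", d$id))
      next
    }
    tmap <- decompose_border_center(patches, cd, ncd)
    death <- segment_death(d$stack, d$pouch,
                           smooth_sigma = config$death_smooth_sigma %||% 0.5,
                           threshold = config$death_threshold)
    dens <- death_density(death, tmap, roi = d$pouch)
    empty <- attr(dens, "empty") %||% character()
    for (sc in names(dens)) {
      quant[[length(quant) + 1L]] <-
        quant_row(d$id, "death_density_pct", sc, unname(dens[sc]), "percent",
                  flag = if (sc %in% empty) "empty_territory" else "")
    }
    if (!("border" %in% empty) && !("center" %in% empty)) {
      border[i] <- dens[["border"]]
      center[i] <- dens[["center"]]
    } else {
      logs <- c(logs, sprintf("%s: empty territory (%s); excluded from pairing",
                              d$id, paste(empty, collapse = ",")))
    }
    logs <- c(logs, sprintf(
      "%s: cell_diameter=%.3g um, %d patch(es), coverage=%.2f%%, death b/c=%.3g/%.3g%%",
      d$id, cd, n_labels(patches), cov,
      dens[["border"]], dens[["center"]]))
  }
  ok <- !is.na(border) & !is.na(center)
  test <- if (sum(ok) >= 2 && any(border[ok] != center[ok]))
    test_row(wilcoxon_signed_rank(border[ok], center[ok]),
             "death_density_pct", "border", "center")
  else
    test_row(NULL, "death_density_pct", "border", "center",
             note = "insufficient n")
  results_table(do.call(rbind, quant), test, logs)
}

#' Run the compartment pipeline on a cohort
#'
#' Per disc: posterior/anterior mean-intensity ratio for the configured
#' channel(s), and optionally per-compartment speckle densities. Cohort
#' level: with a single group, a two-sided one-sample Wilcoxon signed-rank
#' test of the P/A ratios against 1 (the within-disc paired design); with
#' two groups, a two-sided Mann-Whitney U test per metric between them.
#'
#' @param discs list of discs: `list(stack, pouch, compartments, group, id)`;
#'   `compartments` (a [compartment_masks]) defaults to the vertical midline
#'   split of the pouch ([split_compartments()]). Discs whose masks are
#'   missing and not derivable are skipped with a log entry.
#' @param config list: `ratio_roles` (default `"stain"`), `speckle_role`
#'   (optional), `speckle_diameter_range`, `speckle_threshold`.
#' @return a [results_table].
#' @export
run_compartment_pipeline <- function(discs, config = list()) {
  discs <- normalize_discs(discs)
  roles <- config$ratio_roles %||% "stain"
  quant <- list()
  logs <- character()
  ratios <- list()
  groups <- vapply(discs, function(d) d$group %||% "all", character(1))
  for (i in seq_along(discs)) {
    d <- discs[[i]]
    comps <- d$compartments
    if (is.null(comps)) comps <- tryCatch(split_compartments(d$pouch),
                                          error = function(e) NULL)
    if (is.null(comps)) {
      logs <- c(logs, sprintf("%s: missing compartment masks; skipped", d$id))
      next
    }
    for (role in roles) {
      r <- pa_ratio(d$stack, role, comps)
      ratios[[role]] <- rbind(ratios[[role]],
                              data.frame(i = i, group = groups[i], value = r))
      quant[[length(quant) + 1L]] <-
        quant_row(d$id, "pa_ratio", role, r, "ratio")
    }
    if (!is.null(config$speckle_role)) {
      spots <- detect_speckles(
        d$stack, config$speckle_role,
        diameter_range = config$speckle_diameter_range %||% c(0.4, 1.6),
        threshold = config$speckle_threshold)
      for (side in c("anterior", "posterior")) {
        dens <- speckle_density(
          spots, label_mask(comps[[side]], d$stack$voxel_size))
        quant[[length(quant) + 1L]] <-
          quant_row(d$id, "speckle_density", side, dens, "per 1000 um^3")
      }
    }
    logs <- c(logs, sprintf("%s: P/A = %s", d$id,
                            paste(sprintf("%s=%.4g", roles,
                                          vapply(roles, function(rr)
                                            ratios[[rr]]$value[
                                              nrow(ratios[[rr]])],
                                            numeric(1))), collapse = ", ")))
  }
  tests <- list()
  for (role in names(ratios)) {
    rt <- ratios[[role]]
    gs <- unique(rt$group)
    if (length(gs) == 1L) {
      res <- if (nrow(rt) >= 2 && any(rt$value != 1))
        one_sample_wilcoxon(rt$value, mu0 = 1) else NULL
      tests[[length(tests) + 1L]] <-
        test_row(res, "pa_ratio", role, "mu0=1",
                 note = if (is.null(res)) "insufficient n" else "")
    } else if (length(gs) == 2L) {
      res <- mann_whitney_u(rt$value[rt$group == gs[1]],
                            rt$value[rt$group == gs[2]])
      tests[[length(tests) + 1L]] <-
        test_row(res, "pa_ratio", paste0(role, ":", gs[1]),
                 paste0(role, ":", gs[2]))
    }
  }
  results_table(do.call(rbind, quant), do.call(rbind, tests), logs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a results table to CSV + JSON (and optionally a scatter plot)
#'
#' Produces `<prefix>_quant.csv` (long format), `<prefix>_tests.csv` and
#' `<prefix>_summary.json` (per metric x scope n and median, plus the test
#' rows). With `plot = TRUE`, `<prefix>_scatter.png` shows one jittered
#' point per disc with a horizontal line at the median, the convention used
#' for per-disc scatter plots.
#'
#' @param rt a [results_table].
#' @param prefix output path prefix (directories are created).
#' @param plot render the scatter plot.
#' @return named character vector of written paths, invisibly.
#' @export
write_results <- function(rt, prefix, plot = FALSE) {
  stopifnot(inherits(rt, "results_table"))
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  paths <- c(quant = paste0(prefix, "_quant.csv"),
             tests = paste0(prefix, "_tests.csv"),
             summary = paste0(prefix, "_summary.json"))
  write.csv(rt$quant, paths["quant"], row.names = FALSE)
  write.csv(rt$tests, paths["tests"], row.names = FALSE)
  q <- rt$quant
  med <- NULL
  if (nrow(q)) {
    agg <- stats::aggregate(value ~ metric + scope, q, stats::median)
    n <- stats::aggregate(value ~ metric + scope, q, length)
    med <- lapply(seq_len(nrow(agg)), function(i)
      list(metric = agg$metric[i], scope = agg$scope[i],
           median = agg$value[i], n = n$value[i]))
  }
  jsonlite::write_json(list(medians = med,
                            tests = rt$tests, log = rt$log),
                       paths["summary"], auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (plot && nrow(q)) {
    paths <- c(paths, scatter = paste0(prefix, "_scatter.png"))
    grDevices::png(paths["scatter"], width = 900, height = 500)
    on.exit(grDevices::dev.off())
    groups <- interaction(q$metric, q$scope, drop = TRUE)
    gi <- as.integer(groups)
    jit <- with_rng_seed(0L, stats::runif(length(gi), -0.12, 0.12))
    graphics::plot(gi + jit, q$value,
                   xaxt = "n", xlab = "", ylab = "value", pch = 19,
                   col = "grey30", xlim = c(0.5, nlevels(groups) + 0.5))
    graphics::axis(1, at = seq_len(nlevels(groups)),
                   labels = levels(groups), las = 2, cex.axis = 0.7)
    for (g in seq_len(nlevels(groups)))
      graphics::segments(g - 0.25, stats::median(q$value[gi == g]),
                         g + 0.25, stats::median(q$value[gi == g]),
                         lwd = 2, col = "red")
  }
  invisible(paths)
}

#' Read back a results table written by [write_results()]
#' @param prefix the prefix passed to [write_results()].
#' @return a [results_table].
#' @export
read_results <- function(prefix) {
  quant <- read.csv(paste0(prefix, "_quant.csv"),
                    colClasses = c(disc_id = "character", metric = "character",
                                   scope = "character", value = "numeric",
                                   units = "character", flag = "character"))
  quant$flag[is.na(quant$flag)] <- ""
  tests <- read.csv(paste0(prefix, "_tests.csv"),
                    colClasses = c(test_name = "character",
                                   metric = "character", scope_a = "character",
                                   scope_b = "character",
                                   statistic = "numeric", p_value = "numeric",
                                   n = "character", method = "character",
                                   note = "character"))
  tests$note[is.na(tests$note)] <- ""
  summ <- jsonlite::read_json(paste0(prefix, "_summary.json"),
                              simplifyVector = TRUE)
  results_table(quant, tests, summ$log %||% character())
}
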