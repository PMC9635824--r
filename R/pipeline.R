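#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate -> register -> track -> speed on a patch movie,
#' writing every intermediate artifact (TIFF movie, ground-truth JSON,
#' shifts CSV, track CSV, flow CSV) plus a manifest naming each stage's
#' inputs, outputs and the configuration hash. The manifest contains no
#' timestamps, so a rerun with an identical configuration reproduces it
#' byte for byte.
#'
#' @param config list with elements `outdir`, `stages` (subset of
#'   `c("simulate", "register", "track", "speed")` in order), `sim` (a
#'   [sim_config()]), and optionally `registration` (list of
#'   [register_movie()] arguments) and `flow` (a [flow_config()]).
#' @return list with the per-stage results and the manifest (also written
#'   to `manifest.json` in `outdir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$outdir), !is.null(config$stages))
  stages <- config$stages
  known <- c("simulate", "register", "track", "speed")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(config$outdir, ...)
  cfg_json <- jsonlite::toJSON(list(
    stages = stages, sim = unclass(config$sim),
    registration = config$registration, flow = unclass(config$flow)),
    auto_unbox = TRUE, digits = NA)
  cfg_path <- fp("config.json")
  writeLines(cfg_json, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  manifest <- list(config_hash = cfg_hash,
                   package_version = as.character(utils::packageVersion("mtflow")),
                   stages = list())
  results <- list()
  add_stage <- function(name, inputs, outputs) {
    manifest$stages[[name]] <<- list(inputs = inputs, outputs = outputs)
  }
  need <- function(stage, dep, obj) {
    if (is.null(obj))
      stop(sprintf("stage '%s' needs the output of stage '%s', which is disabled and was not found on disk",
                   stage, dep))
    obj
  }
  sim <- NULL; movie <- NULL; gt <- NULL
  if ("simulate" %in% stages) {
    sim <- simulate_patch_movie(config$sim)
    movie <- sim$movie; gt <- sim$ground_truth
    write_movie_tiff(movie, fp("movie.tif"))
    write_ground_truth_json(
      list(patch_speed_um_min = gt$patch_speed_um_min,
           patch_positions_um = gt$patch_positions_um,
           jitter_px = gt$jitter_px, time_min = gt$time_min),
      fp("ground_truth.json"))
    add_stage("simulate", inputs = "config.json",
              outputs = c("movie.tif", "ground_truth.json"))
    results$simulate <- sim
  }
  reg <- NULL
  if ("register" %in% stages) {
    if (is.null(movie) && file.exists(fp("movie.tif")))
      movie <- read_movie_tiff(fp("movie.tif"))
    movie <- need("register", "simulate", movie)
    reg_args <- c(list(movie = movie), config$registration)
    reg <- do.call(register_movie, reg_args)
    write_movie_tiff(reg$movie, fp("registered.tif"))
    utils::write.csv(reg$shifts, fp("shifts.csv"), row.names = FALSE)
    add_stage("register", inputs = "movie.tif",
              outputs = c("registered.tif", "shifts.csv"))
    results$register <- reg
  }
  track <- NULL
  if ("track" %in% stages) {
    rmv <- need("track", "register", reg)$movie
    path <- need("track", "simulate", gt)$paths[[1]]
    track <- track_patch(rmv, path)
    utils::write.csv(track, fp("track.csv"), row.names = FALSE)
    add_stage("track", inputs = c("registered.tif"), outputs = "track.csv")
    results$track <- track
  }
  if ("speed" %in% stages) {
    track <- need("speed", "track", track)
    fm <- speed_from_track(track, config$flow %||% flow_config())
    utils::write.csv(
      data.frame(method = "patch", speed_um_min = fm$speed_um_min,
                 direction = fm$direction, duration_min = fm$duration_min),
      fp("flow.csv"), row.names = FALSE)
    add_stage("speed", inputs = "track.csv", outputs = "flow.csv")
    results$speed <- fm
  }
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  results$manifest <- manifest
  results
}

#' Compare groups with the study's standard statistics
#'
#' More than two independent groups: Kruskal-Wallis gate at `alpha`, then
#' all pairwise Dunn tests with Bonferroni correction. Two paired groups:
#' Wilcoxon signed-rank. Two independent groups: Kruskal-Wallis (equivalent
#' to a rank-sum test).
#'
#' @param values numeric vector of observations.
#' @param groups factor/character of the same length.
#' @param design `"independent"` or `"paired"` (paired requires exactly two
#'   groups in matching order).
#' @param alpha gate level for the omnibus test (default 0.05).
#' @return list with `omnibus` (test name, statistic, p), `pairs` (data
#'   frame of pairwise comparisons with adjusted p, or NULL), `flagged`
#'   (pairs significant at `alpha` after correction).
#' @export
group_compare <- function(values, groups, design = c("independent", "paired"),
                          alpha = 0.05) {
  design <- match.arg(design)
  groups <- as.factor(groups)
  k <- nlevels(groups)
  if (design == "paired") {
    if (k != 2L) stop("paired design requires exactly two groups")
    a <- values[groups == levels(groups)[1]]
    b <- values[groups == levels(groups)[2]]
    if (length(a) != length(b)) stop("paired groups must have equal size")
    d <- a - b
    if (all(d == 0)) {
      # all-zero differences carry no signed-rank information; p = 1 by
      # convention
      return(list(omnibus = list(test = "wilcoxon_signed_rank",
                                 statistic = 0, p = 1),
                  pairs = NULL, flagged = character(0)))
    }
    # ties or zero differences force the normal approximation silently
    use_exact <- length(d) < 25 && !any(d == 0) && !any(duplicated(abs(d)))
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = use_exact))
    return(list(omnibus = list(test = "wilcoxon_signed_rank",
                               statistic = unname(wt$statistic),
                               p = wt$p.value),
                pairs = NULL,
                flagged = if (wt$p.value < alpha)
                  paste(levels(groups), collapse = " vs ") else character(0)))
  }
  kw <- stats::kruskal.test(values, groups)
  res <- list(omnibus = list(test = "kruskal_wallis",
                             statistic = unname(kw$statistic),
                             p = kw$p.value),
              pairs = NULL, flagged = character(0))
  if (k > 2L && kw$p.value < alpha) {
    res$pairs <- dunn_test(values, groups, p_adjust = "bonferroni")
    res$flagged <- with(res$pairs,
                        paste(group1, "vs", group2)[p_adjusted < alpha])
  }
  res
}

#' Dunn's post hoc test
#'
#' All-pairs z-tests on mean ranks after a Kruskal-Wallis test, with the
#' standard tie correction and the requested p-value adjustment.
#'
#' @param values numeric vector.
#' @param groups factor of the same length.
#' @param p_adjust method passed to [stats::p.adjust()].
#' @return data frame `(group1, group2, z, p, p_adjusted)`.
#' @export
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  groups <- droplevels(as.factor(groups))
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  out <- list()
  for (i in seq_len(length(lv) - 1L)) {
    for (j in (i + 1L):length(lv)) {
      se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                   (1 / n[[lv[i]]] + 1 / n[[lv[j]]]))
      z <- (rbar[[lv[i]]] - rbar[[lv[j]]]) / se
      p <- 2 * stats::pnorm(-abs(z))
      out[[length(out) + 1L]] <- data.frame(group1 = lv[i], group2 = lv[j],
                                            z = z, p = p)
    }
  }
  df <- do.call(rbind, out)
  df$p_adjusted <- pmin(stats::p.adjust(df$p, method = p_adjust), 1)
  df
}
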