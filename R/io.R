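#' Load a panel of ROI time series from delimited files
#'
#' Reads one delimited text file per individual (rows = scans, columns =
#' ROIs). The field separator and the presence of a header row are
#' auto-detected per file; configured missing-value codes become `NA`
#' placeholders. All files must agree on the ROI count.
#'
#' @param directory path containing the series files.
#' @param roi_labels optional ROI names; defaults to the first file's
#'   header (if any) or `ROI01`-style labels.
#' @param pattern regular expression selecting series files.
#' @param missing_codes strings treated as missing values.
#' @return a [ts_panel()]; IDs are the file names without extension.
#' @export
load_panel <- function(directory, roi_labels = NULL,
                       pattern = "\\.(csv|tsv|txt)$",
                       missing_codes = c("NA", "NaN", "nan", ".", "")) {
  files <- sort(list.files(directory, pattern = pattern, full.names = TRUE))
  if (!length(files))
    stop("no time-series files matching '", pattern, "' in ", directory)
  series <- vector("list", length(files))
  headers <- NULL
  for (i in seq_along(files)) {
    parsed <- read_delim_matrix(files[i], missing_codes)
    series[[i]] <- parsed$mat
    if (i == 1L) headers <- parsed$header
  }
  ncols <- vapply(series, ncol, 0L)
  if (length(unique(ncols)) > 1L) {
    off <- basename(files)[ncols != ncols[1L]]
    stop("inconsistent ROI counts across files: ",
         paste(off, collapse = ", "))
  }
  if (is.null(roi_labels)) roi_labels <- headers
  ts_panel(series, ids = sub("\\.[^.]+$", "", basename(files)),
           roi_labels = roi_labels)
}

# Sniffs separator (tab, comma, semicolon, whitespace) and header row.
read_delim_matrix <- function(path, missing_codes) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty file: ", path)
  sep <- if (grepl("\t", first)) "\t"
         else if (grepl(",", first)) ","
         else if (grepl(";", first)) ";"
         else ""
  probe <- utils::read.table(path, sep = sep, header = FALSE,
                             na.strings = missing_codes, nrows = 1L,
                             colClasses = "character",
                             stringsAsFactors = FALSE)
  vals <- unlist(probe)
  suppressWarnings(nums <- as.numeric(vals))
  # a header cell is a non-missing string that fails numeric conversion;
  # missing-coded cells are data (e.g. an all-scrubbed first frame)
  header <- any(is.na(nums) & !is.na(vals))
  df <- utils::read.table(path, sep = sep, header = header,
                          na.strings = missing_codes)
  mat <- as.matrix(df)
  storage.mode(mat) <- "double"
  list(mat = mat, header = if (header) colnames(df))
}

#' Framewise displacement from realignment parameters
#'
#' `FD_i = |d_ix - d_(i-1)x| + |d_iy - d_(i-1)y| + |d_iz - d_(i-1)z| +
#' |alpha_i - alpha_(i-1)| + |beta_i - beta_(i-1)| + |gamma_i -
#' gamma_(i-1)|`: the sum of absolute backward differences of the six
#' rigid-body motion parameters (3 translations, 3 rotations), with
#' `FD_1 = 0`. Rotational parameters are assumed already expressed in
#' millimeters (converted on a sphere), as is conventional.
#'
#' @param realignment T x 6 numeric matrix of motion parameters.
#' @return numeric vector of length T.
#' @export
compute_fd <- function(realignment) {
  rp <- as.matrix(realignment)
  if (ncol(rp) != 6L)
    stop("realignment parameters must have 6 columns, got ", ncol(rp))
  if (nrow(rp) < 2L) stop("need at least 2 frames")
  c(0, rowSums(abs(diff(rp))))
}

#' Scrub high-motion frames from a series
#'
#' Frames whose framewise displacement exceeds `threshold` are replaced
#' by all-`NA` placeholder rows, so the temporal ordering of scans is
#' retained for the lagged model (pairs spanning a scrubbed frame are
#' simply dropped at estimation).
#'
#' @param ts T x p series matrix.
#' @param fd framewise displacement per frame ([compute_fd()]).
#' @param threshold scrub frames with `fd > threshold` (default 0.2 mm).
#' @return the series with placeholder rows, attribute `n_scrubbed`.
#' @export
scrub_frames <- function(ts, fd, threshold = 0.2) {
  ts <- as.matrix(ts)
  if (length(fd) != nrow(ts))
    stop("fd length (", length(fd), ") != number of frames (", nrow(ts), ")")
  bad <- fd > threshold
  ts[bad, ] <- NA_real_
  structure(ts, n_scrubbed = sum(bad))
}

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline in one serializable list:
#' the GIMME majority proportion and alpha, the threshold grid and run
#' counts for subgroup detection, the perturbation levels and replicate
#' count for the robustness check, the FD scrub threshold, the
#' subgroup-comparison alpha and FDR method, and the master seed.
#'
#' @param ... name-value overrides of the defaults.
#' @return list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    gimme = list(gamma = 0.75, alpha = 0.05, standardize = FALSE),
    subgroup = list(grid_from = 0, grid_to = 1, grid_by = 0.01, runs = 100),
    robustness = list(enabled = TRUE, level_by = 0.025, reps = 100,
                      baseline = TRUE),
    compare = list(alpha = 0.05, method = "storey"),
    scrub = list(fd_threshold = 0.2),
    simulation = NULL)
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  structure(cfg, class = "run_config")
}


#' Read / write a pipeline configuration
#'
#' YAML round-trip of a [default_config()] list; unknown keys are
#' preserved, missing keys filled with defaults.
#'
#' @param path YAML file path.
#' @return a `run_config` (for `read_config`); `path` invisibly (for
#'   `write_config`).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- unclass(default_config())
  for (nm in names(raw)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(raw[[nm]]))
      utils::modifyList(cfg[[nm]], raw[[nm]]) else raw[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full subgrouping pipeline
#'
#' Drives every stage on a supplied or simulated panel: (optional)
#' simulation, two-stage GIMME search, similarity construction with
#' data-driven threshold selection and community detection, the
#' degree-preserving robustness check (with a matched random-graph
#' baseline), and the subgroup path-weight comparison. All randomness is
#' governed by `config$seed`. When `out_dir` is given, each artifact is
#' written as delimited text.
#'
#' @param config a [default_config()] / [read_config()] list. When
#'   `config$simulation` is a [simulation_design()] (or a list of its
#'   arguments), the panel is simulated; otherwise supply `panel`.
#' @param panel a [ts_panel()] of observed ROI series (ignored when
#'   simulating).
#' @param out_dir optional output directory for the artifact files.
#' @param verbose print stage progress?
#' @return list of class `pipeline_result`: `maps`, `subgroups`,
#'   `robustness` (and `robustness_baseline`), `comparison`, `truth`
#'   (simulated runs only), `accuracy`/`recovery` (simulated runs only),
#'   `config`.
#' @export
run_pipeline <- function(config = default_config(), panel = NULL,
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  if (!is.null(config$seed)) set.seed(config$seed)
  truth <- NULL
  if (!is.null(config$simulation)) {
    des <- config$simulation
    if (!inherits(des, "sim_design"))
      des <- do.call(simulation_design, des)
    say("simulating ", des$n_individuals, " individuals")
    sim <- generate_panel(des)
    panel <- sim$panel; truth <- sim$truth
  }
  if (is.null(panel)) stop("supply `panel` or a simulation design in config")

  say("GIMME group search")
  gm <- run_group_search(panel, gamma = config$gimme$gamma,
                         alpha = config$gimme$alpha,
                         standardize = config$gimme$standardize)
  say("GIMME individual search")
  maps <- run_individual_search(panel, gm, alpha = config$gimme$alpha)

  say("subgroup detection")
  grid <- seq(config$subgroup$grid_from, config$subgroup$grid_to,
              by = config$subgroup$grid_by)
  sg <- detect_subgroups(maps, grid = grid, runs = config$subgroup$runs)

  rob <- rob_base <- NULL
  if (isTRUE(config$robustness$enabled)) {
    say("robustness check")
    levels <- seq(0, 1, by = config$robustness$level_by)
    rob <- robustness_curve(sg$adjacency, sg$partition, levels = levels,
                            reps = config$robustness$reps)
    if (isTRUE(config$robustness$baseline)) {
      B <- random_baseline(sg$adjacency)
      rob_base <- robustness_curve(B, levels = levels,
                                   reps = config$robustness$reps)
    }
  }

  say("subgroup comparison")
  comparison <- compare_subgroup_paths(sg$betas, sg$partition,
                                       alpha = config$compare$alpha,
                                       method = config$compare$method)

  res <- structure(
    list(maps = maps, subgroups = sg, robustness = rob,
         robustness_baseline = rob_base, comparison = comparison,
         truth = truth, config = config),
    class = "pipeline_result")
  if (!is.null(truth)) {
    keep <- match(maps$ids, truth$ids)
    res$accuracy <- subgroup_accuracy(sg$partition$membership,
                                      truth$labels[keep])
    res$recovery <- recovery_accuracy(maps, truth)
  }
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n  ")
  print(x$maps)
  cat("  r* = ", format(unclass(x$subgroups$r_star)), "; ", sep = "")
  print(x$subgroups$partition)
  if (!is.null(x$accuracy))
    cat("  subgroup accuracy vs ground truth: ",
        sprintf("%.2f%%", 100 * as.numeric(x$accuracy)),
        "; connection recovery: ",
        sprintf("%.2f%%", 100 * as.numeric(x$recovery)), "\n", sep = "")
  invisible(x)
}

# Write the artifact bundle as delimited text files.
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  maps <- res$maps
  edges <- do.call(rbind, lapply(maps$ids, function(id) {
    fit <- maps$fits[[id]]
    e <- rbind(edge_table(fit$A_hat * fit$spec$free_A, lag = 0L),
               edge_table(fit$Phi_hat * fit$spec$free_Phi, lag = 1L))
    if (!nrow(e)) return(NULL)
    lvl <- ifelse(e$lag == 0L,
                  ifelse(maps$group_map$free_A[cbind(e$to, e$from)],
                         "group", "individual"),
                  ifelse(maps$group_map$free_Phi[cbind(e$to, e$from)],
                         "group", "individual"))
    cbind(individual = id, e, level = lvl)
  }))
  wt(edges, "edges.tsv")
  X <- res$subgroups$network$X
  utils::write.table(round(X, 6), file.path(out_dir, "similarity.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  wt(data.frame(individual = res$subgroups$ids,
                community = res$subgroups$partition$membership),
     "partition.tsv")
  wt(res$subgroups$scan$table, "threshold_scan.tsv")
  if (!is.null(res$robustness)) wt(res$robustness$table, "robustness.tsv")
  if (!is.null(res$robustness_baseline))
    wt(res$robustness_baseline$table, "robustness_baseline.tsv")
  wt(res$comparison$contrasts, "comparison.tsv")
  wt(res$comparison$anova, "anova.tsv")
  log <- c(paste0("gimmeclust ", as.character(utils::packageVersion("gimmeclust"))),
           paste0("seed: ", res$config$seed),
           paste0("r_star: ", format(unclass(res$subgroups$r_star))),
           paste0("Q: ", format(res$subgroups$partition$Q)),
           paste0("subgroup sizes: ",
                  paste(tabulate(res$subgroups$partition$membership),
                        collapse = ", ")))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
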