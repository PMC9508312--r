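#' Default run configuration
#'
#' Returns the fully resolved default configuration for [run_pipeline()] as
#' a named list; any subset of fields can be overridden via `...` (or by
#' passing a JSON file path to [run_pipeline()]).
#'
#' @param ... overrides merged over the defaults (top-level fields).
#' @return named list of class `pdc_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    mode = "synthetic",                     # synthetic | matrix
    seed = 1L,
    cohort = list(n_patients = 19, n_controls = 20, attenuation = 0.3,
                  duration_s = 240, fs = 500,
                  hdrs_model = NULL),
    base_spec = NULL,                       # path to a spec JSON, or NULL
    subjects = NULL,                        # matrix mode: data.frame/file
    schedule = NULL,                        # matrix mode: EC/EO segments
    reference = character(),                # labels to re-reference against
    bandpass = c(0.1, 100),                 # Hz, NULL to skip
    resample_to = NULL,                     # Hz, NULL to skip
    bands = list(alpha = c(8, 13), beta = c(13, 30), gamma = c(30, 50)),
    freq_grid = c(lo = 1, hi = 50, step = 0.5),
    mvar = list(order = "auto", max_order = 20),
    block_band = "alpha",
    condition = "EC",
    cor_scope = "all",                      # all | patients
    cor_metrics = c("C", "L", "LL", "RL"),
    output_dir = NULL,
    export_threshold = NULL
  )
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  class(cfg) <- c("pdc_config", "list")
  cfg
}

#' Validate a run configuration
#'
#' Structural checks before any computation: known mode, usable frequency
#' grid below Nyquist, band edges inside the grid, MVAR order sane, and
#' matrix-mode inputs present when selected.
#'
#' @param cfg a config list (from [default_config()] or JSON).
#' @return the config, invisibly; errors describe the offending field.
#' @export
validate_config <- function(cfg) {
  if (!cfg$mode %in% c("synthetic", "matrix")) {
    stop("config$mode must be 'synthetic' or 'matrix'")
  }
  fg <- cfg$freq_grid
  if (!(fg[["lo"]] > 0 && fg[["hi"]] > fg[["lo"]] && fg[["step"]] > 0)) {
    stop("config$freq_grid must satisfy 0 < lo < hi, step > 0")
  }
  fs <- if (cfg$mode == "synthetic") cfg$cohort$fs
        else if (!is.null(cfg$resample_to)) cfg$resample_to else NA
  if (is.finite(fs) && fg[["hi"]] >= fs / 2) {
    stop("frequency grid reaches the Nyquist frequency; lower freq_grid$hi")
  }
  for (b in names(cfg$bands)) {
    e <- cfg$bands[[b]]
    if (!(e[1] < e[2])) stop("band ", b, " has f_lo >= f_hi")
  }
  if (!cfg$block_band %in% names(cfg$bands)) {
    stop("config$block_band must name one of the configured bands")
  }
  ord <- cfg$mvar$order
  if (!(identical(ord, "auto") || (is.numeric(ord) && ord >= 1))) {
    stop("config$mvar$order must be 'auto' or a positive integer")
  }
  if (cfg$mode == "matrix" && is.null(cfg$subjects)) {
    stop("matrix mode needs config$subjects")
  }
  if (!cfg$cor_scope %in% c("all", "patients")) {
    stop("config$cor_scope must be 'all' or 'patients'")
  }
  invisible(cfg)
}

#' Read a run configuration from JSON
#' @param path JSON file path.
#' @return a `pdc_config` list (defaults merged under the file's fields).
#' @export
read_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(default_config, obj)
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Analyze one recording into connectivity, metrics, and blocks
#'
#' The per-subject core of the pipeline: fit the MVAR model, evaluate PDC on
#' the frequency grid, band-average each configured band, and compute graph
#' metrics and block sums on the `block_band` network.
#'
#' @param rec a preprocessed `pdc_recording`.
#' @param cfg a validated `pdc_config`.
#' @param montage montage for block summaries.
#' @return list: `model` order/spectral radius summary, `conn` (list of
#'   `pdc_connectivity` per band), `mean_pdc` per band, `metrics`
#'   (from [network_metrics()]), `blocks` (from [summarize_blocks()]).
#' @export
analyze_recording <- function(rec, cfg = default_config(),
                              montage = montage_1020_30()) {
  fg <- cfg$freq_grid
  freqs <- seq(fg[["lo"]], fg[["hi"]], by = fg[["step"]])
  model <- fit_mvar(rec, order = cfg$mvar$order,
                    max_order = cfg$mvar$max_order)
  spec <- pdc(model, freqs, rec$fs)
  conn <- lapply(names(cfg$bands), function(b) {
    band_average(spec, band_spec(b, cfg$bands[[b]][1], cfg$bands[[b]][2]),
                 condition = rec$condition)
  })
  names(conn) <- names(cfg$bands)
  mp <- vapply(conn, mean_pdc, numeric(1))
  main <- conn[[cfg$block_band]]
  list(model = list(order = model$order,
                    spectral_radius = model$spectral_radius),
       conn = conn, mean_pdc = mp,
       metrics = network_metrics(main),
       blocks = summarize_blocks(main, montage))
}

.load_matrix_subjects <- function(cfg) {
  subj <- cfg$subjects
  if (is.character(subj)) {
    subj <- utils::read.table(subj, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  }
  recs <- vector("list", nrow(subj))
  for (i in seq_len(nrow(subj))) {
    r <- read_recording(subj$path[i], fs = subj$fs[i],
                        subject_id = subj$id[i], group = subj$group[i])
    if (length(cfg$reference) > 0) r <- rereference(r, cfg$reference)
    if (!is.null(cfg$bandpass)) {
      hi <- min(cfg$bandpass[2], 0.99 * r$fs / 2)
      r <- bandpass(r, cfg$bandpass[1], hi)
    }
    if (!is.null(cfg$resample_to)) r <- resample_recording(r, cfg$resample_to)
    if (!is.null(cfg$schedule)) {
      parts <- split_conditions(r, session_schedule(cfg$schedule))
      r <- parts[[cfg$condition]]
      if (is.null(r)) stop("no ", cfg$condition, " segments for subject ",
                           subj$id[i])
    }
    recs[[i]] <- r
  }
  list(recordings = recs,
       meta = data.frame(id = subj$id, group = subj$group,
                         hdrs = subj$hdrs, seed = NA_integer_))
}

#' Run the full directed-network analysis
#'
#' Orchestrates the end-to-end pipeline: obtain per-subject recordings
#' (synthetic cohort or delimited-matrix inputs), analyze each subject
#' ([analyze_recording()]), then run the group statistics -- band-wise mean
#' PDC t-tests, global metric t-tests, hemispheric/midline/regional block
#' t-tests (each its own FDR family) -- and the HDRS correlations.  A
#' subject whose analysis fails is skipped with a logged reason, never
#' silently dropped.
#'
#' @param cfg a `pdc_config` list, or path to a JSON config file.
#' @param montage montage used for block analyses.
#' @return list of class `pdc_result`: `meta`, `subject_log`, `mean_pdc`
#'   (subjects x bands), `metrics` (per-subject globals), `node_metrics`,
#'   `blocks` (per-subject block values), `stats` (list of group-comparison
#'   tables), `correlations`, `config_hash`, `config`.
#' @export
run_pipeline <- function(cfg = default_config(),
                         montage = montage_1020_30()) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  if (cfg$mode == "synthetic") {
    ch <- cfg$cohort
    base <- if (is.null(cfg$base_spec)) default_base_spec(ch$fs)
            else spec_from_json(cfg$base_spec)
    cohort <- cohort_spec(n_patients = ch$n_patients,
                          n_controls = ch$n_controls,
                          attenuation = ch$attenuation,
                          hdrs_model = ch$hdrs_model,
                          duration_s = ch$duration_s, fs = ch$fs,
                          seed = cfg$seed)
    sim <- simulate_cohort(cohort, base)
    recs <- sim$recordings
    meta <- sim$meta
  } else {
    loaded <- .load_matrix_subjects(cfg)
    recs <- loaded$recordings
    meta <- loaded$meta
  }

  n <- length(recs)
  log <- data.frame(id = meta$id, status = "ok", reason = "",
                    stringsAsFactors = FALSE)
  per <- vector("list", n)
  for (i in seq_len(n)) {
    per[[i]] <- tryCatch(analyze_recording(recs[[i]], cfg, montage),
                         error = function(e) e)
    if (inherits(per[[i]], "error")) {
      log$status[i] <- "skipped"
      log$reason[i] <- conditionMessage(per[[i]])
      per[i] <- list(NULL)
    }
  }
  ok <- !vapply(per, is.null, logical(1))
  per <- per[ok]
  meta_ok <- meta[ok, , drop = FALSE]

  mp <- do.call(rbind, lapply(per, function(x) x$mean_pdc))
  rownames(mp) <- meta_ok$id
  glob <- data.frame(
    C = vapply(per, function(x) x$metrics$C, numeric(1)),
    L = vapply(per, function(x) x$metrics$L, numeric(1)),
    Ge = vapply(per, function(x) x$metrics$Ge, numeric(1)),
    row.names = meta_ok$id
  )
  node <- do.call(rbind, lapply(seq_along(per), function(i) {
    cbind(subject = meta_ok$id[i], per[[i]]$metrics$per_node)
  }))
  blk <- do.call(rbind, lapply(per, function(x) {
    c(x$blocks$hemisphere, x$blocks$region)
  }))
  rownames(blk) <- meta_ok$id
  sizes <- per[[1L]]$blocks$sizes

  grp <- meta_ok$group
  stats_out <- if (min(sum(grp == "control"), sum(grp == "patient")) < 2) {
    list()
  } else list(
    mean_pdc = group_compare(as.data.frame(mp), grp, family = "bands"),
    global_metrics = group_compare(glob, grp, family = "global_metrics"),
    hemisphere = group_compare(
      as.data.frame(blk[, c("LL", "LR", "RL", "RR"), drop = FALSE]),
      grp, family = "hemisphere"),
    midline = group_compare(
      as.data.frame(blk[, c("MM", "LM", "ML", "RM", "MR"), drop = FALSE]),
      grp, family = "midline"),
    regions = group_compare(
      as.data.frame(blk[, setdiff(colnames(blk),
                                  c("LL", "LR", "RL", "RR", "MM", "LM",
                                    "ML", "RM", "MR")), drop = FALSE]),
      grp, family = "regions")
  )

  sel <- if (cfg$cor_scope == "patients") grp == "patient" else rep(TRUE, nrow(meta_ok))
  cors <- lapply(cfg$cor_metrics, function(m) {
    v <- if (m %in% colnames(glob)) glob[[m]]
         else blk[, m] / sizes[[m]]   # per-edge normalized block value
    tryCatch(pearson_with_fit(meta_ok$hdrs[sel], v[sel]),
             error = function(e) NULL)
  })
  names(cors) <- cfg$cor_metrics
  keep <- !vapply(cors, is.null, logical(1))
  cor_tab <- if (any(keep)) {
    data.frame(
      metric = names(cors)[keep],
      r = vapply(cors[keep], function(x) x$r, numeric(1)),
      p = vapply(cors[keep], function(x) x$p, numeric(1)),
      slope = vapply(cors[keep], function(x) x$slope, numeric(1)),
      intercept = vapply(cors[keep], function(x) x$intercept, numeric(1)),
      n = vapply(cors[keep], function(x) x$n, numeric(1))
    )
  } else data.frame()
  if (nrow(cor_tab) > 0) {
    cor_tab$p_corrected <- as.numeric(bh_fdr(cor_tab$p,
                                             family = "correlations"))
  }

  res <- structure(
    list(meta = meta_ok, subject_log = log, mean_pdc = mp, metrics = glob,
         node_metrics = node, blocks = blk, block_sizes = sizes,
         stats = stats_out, correlations = cor_tab,
         per_subject = per,
         config_hash = .config_hash(cfg), config = cfg),
    class = "pdc_result"
  )
  if (!is.null(cfg$output_dir)) write_result(res, cfg$output_dir)
  res
}

#' @export
print.pdc_result <- function(x, ...) {
  cat(sprintf("<pdc_result> %d subjects analyzed (%d skipped), band '%s'\n",
              nrow(x$meta), sum(x$subject_log$status != "ok"),
              x$config$block_band))
  cat("  config hash:", x$config_hash, "\n")
  invisible(x)
}

#' Write the result bundle as delimited tables
#'
#' Every table carries the config hash in a sidecar `run_info.json` along
#' with the package version and timestamp.
#'
#' @param res a `pdc_result`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t",
    row.names = FALSE, quote = FALSE)
  wt(cbind(subject = rownames(res$mean_pdc), as.data.frame(res$mean_pdc)),
     "mean_pdc.tsv")
  wt(cbind(subject = rownames(res$metrics), res$metrics),
     "global_metrics.tsv")
  wt(res$node_metrics, "node_metrics.tsv")
  wt(cbind(subject = rownames(res$blocks), as.data.frame(res$blocks)),
     "blocks.tsv")
  for (nm in names(res$stats)) wt(res$stats[[nm]], paste0("stats_", nm, ".tsv"))
  if (nrow(res$correlations) > 0) wt(res$correlations, "correlations.tsv")
  wt(res$meta, "subjects.tsv")
  wt(res$subject_log, "subject_log.tsv")
  info <- list(config_hash = res$config_hash,
               package_version = as.character(utils::packageVersion("pdcnet")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               config = unclass(res$config))
  writeLines(jsonlite::toJSON(info, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE),
             file.path(dir, "run_info.json"))
  invisible(dir)
}

#' Export a connectivity matrix and its edge list
#'
#' The full matrix is always written unthresholded; the edge list keeps
#' edges with weight strictly above `threshold` (a display filter -- e.g.
#' 0.172 reproduces a sparse view of a dense alpha-band network).
#'
#' @param mat a `pdc_connectivity`.
#' @param prefix output path prefix; writes `<prefix>_matrix.csv` and
#'   `<prefix>_edges.csv`.
#' @param threshold minimal retained edge weight, or `NULL` to keep all
#'   non-zero edges.
#' @return invisibly, the edge-list data.frame (`source`, `target`,
#'   `weight`).
#' @export
export_network <- function(mat, prefix, threshold = NULL) {
  W <- .conn_weights(mat)
  utils::write.csv(W, paste0(prefix, "_matrix.csv"))
  thr <- if (is.null(threshold)) 0 else threshold
  if (thr < 0) stop("threshold must be >= 0")
  idx <- which(W > thr & row(W) != col(W), arr.ind = TRUE)
  edges <- data.frame(source = colnames(W)[idx[, "col"]],
                      target = rownames(W)[idx[, "row"]],
                      weight = W[idx])
  edges <- edges[order(-edges$weight), , drop = FALSE]
  rownames(edges) <- NULL
  utils::write.csv(edges, paste0(prefix, "_edges.csv"), row.names = FALSE)
  invisible(edges)
}
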