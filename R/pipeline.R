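# End-to-end orchestration: simulate -> preprocess -> features -> cluster ->
# validate-k -> loo -> infoshare -> report, from a single validated config
# with a master seed, structured stderr logging, and a JSON run manifest
# (config hash, stage timings, output digests). Stages are resumable: when a
# stage's outputs already exist with digests recorded under the same config
# hash, the stage is skipped and its outputs are reloaded where downstream
# stages need them.

#' Default pipeline configuration
#'
#' Every default matches the canonical analysis values where one exists:
#' 1-100 Hz band-pass with 49-51 Hz notch, -1000..2000 ms epochs, 500 uV
#' rejection, N2 ROI 250-400 ms on FL2/FR2/PL1/PR1, gamma ROI 55-90 Hz x
#' 200-500 ms, ordinal m = 3, tau = 1, window = 256, 100 k-means runs,
#' k grid {3, 4, 5}, KSG k = 5. Simulation sizes are desk-scale defaults.
#'
#' @param seed master seed (fans out to per-stage, per-run seeds).
#' @param out_dir output directory.
#' @param ... overrides for any top-level field.
#' @return validated `run_config` list.
#' @export
default_config <- function(seed = 1, out_dir = "nocistate_run", ...) {
  cfg <- list(
    seed = seed, out_dir = out_dir,
    montage = default_montage(),
    n_subjects = 6, trials_per_subject = 32, isi_s = 4,
    filter = list(band = c(1, 100), notch = c(49, 51), order = 4),
    window = c(-1000, 2000), baseline = c(-1000, 0), reject_uv = 500,
    n2_roi = c(250, 400), n2_electrodes = n2_electrodes(),
    gbo_band = c(55, 90), gbo_twin = c(200, 500),
    pe_twin = c(0, 1000), pe_electrodes = pe_electrodes(),
    pcmi_twin = c(0, 500), pcmi_electrodes = frontal_electrodes(),
    ordinal = list(m = 3, tau = 1, window = 256), pe_step = 10,
    k = 4, runs = 100, n_boot = 100, k_grid = c(3, 4, 5),
    ksg_k = 5, write_recordings = FALSE)
  cfg <- modifyList(cfg, list(...))
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  ok <- function(test, msg) if (!test) stop_bad_arg(paste("config:", msg))
  ok(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be scalar")
  ok(cfg$filter$band[1] > 0 && cfg$filter$band[1] < cfg$filter$band[2],
     "filter band must be increasing and positive")
  ok(cfg$window[1] <= 0 && cfg$window[2] >= 0, "epoch window must span 0")
  ok(cfg$reject_uv > 0, "rejection threshold must be positive")
  ok(cfg$ordinal$m >= 2 && cfg$ordinal$tau >= 1, "bad ordinal parameters")
  ok(all(cfg$k_grid >= 2), "k_grid entries must be >= 2")
  ok(cfg$runs >= 1 && cfg$n_boot >= 1, "runs and n_boot must be >= 1")
  invisible(cfg)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(unclass(cfg)), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

log_line <- function(stage, level, msg, ...) {
  kv <- list(...)
  extra <- if (length(kv))
    paste(sprintf("%s=%s", names(kv), unlist(kv)), collapse = " ") else ""
  message(sprintf("[%s] %s %s %s", stage, level, msg, extra))
}

manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

read_manifest <- function(out_dir) {
  p <- manifest_path(out_dir)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else NULL
}

outputs_current <- function(manifest, cfg_hash, stage, files) {
  if (is.null(manifest) || !identical(manifest$config_hash, cfg_hash)) return(FALSE)
  entry <- manifest$stages[[stage]]
  if (is.null(entry)) return(FALSE)
  if (!all(file.exists(files))) return(FALSE)
  recorded <- unlist(entry$outputs)
  current <- unname(tools::md5sum(files))
  identical(unname(recorded[basename(files)]), current)
}

#' Run the analysis pipeline
#'
#' @param config a `run_config` from [default_config()].
#' @param stages character vector of stages to run, in order; default all.
#' @return invisible list with the in-memory stage products (`cohort`,
#'   `epochs`, `features`, `solution`, `bootstrap`, `loo`, `sharing`,
#'   `report`) plus the manifest.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "preprocess", "features",
                                    "cluster", "validate_k", "loo",
                                    "infoshare", "report")) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- config_hash(config)
  manifest <- read_manifest(config$out_dir)
  if (!is.null(manifest) && !identical(manifest$config_hash, cfg_hash))
    manifest <- NULL  # config changed: nothing is current
  new_manifest <- list(config_hash = cfg_hash, seed = config$seed,
                       stages = list())
  st <- new.env(parent = emptyenv())
  out <- function(...) file.path(config$out_dir, ...)
  p <- ordinal_params(config$ordinal$m, config$ordinal$tau,
                      config$ordinal$window)

  finish <- function(stage, files, t0, skipped = FALSE) {
    digests <- as.list(tools::md5sum(files))
    names(digests) <- basename(files)
    new_manifest$stages[[stage]] <<- list(
      skipped = skipped, seconds = round(as.numeric(Sys.time()) - t0, 2),
      outputs = digests)
    log_line(stage, "info", if (skipped) "skipped (outputs current)" else "done",
             seconds = round(as.numeric(Sys.time()) - t0, 1))
  }

  need <- function(what, stage_hint) {
    if (!is.null(st[[what]])) return(st[[what]])
    stop_bad_arg(sprintf("missing upstream product '%s': run stage '%s' first",
                         what, stage_hint))
  }

  for (stage in stages) {
    t0 <- as.numeric(Sys.time())
    switch(stage,
      simulate = {
        files <- out("events.tsv")
        st$cohort <- generate_cohort(
          n_subjects = config$n_subjects,
          trials_per_subject = config$trials_per_subject,
          seed = derive_seed(config$seed, "simulate"),
          isi_s = config$isi_s, channel_labels = config$montage)
        write_events_tsv(st$cohort$events, out("events.tsv"))
        if (isTRUE(config$write_recordings)) {
          for (rec in st$cohort$recordings) {
            f <- out(sprintf("recording_%s.tsv", rec$subject_id))
            write_recording_tsv(rec, f)
            files <- c(files, f)
          }
        }
        finish(stage, files, t0)
      },
      preprocess = {
        cohort <- need("cohort", "simulate")
        st$epochs <- preprocess_cohort(
          cohort, band = config$filter$band, notch = config$filter$notch,
          order = config$filter$order, window = config$window,
          baseline = config$baseline, threshold = config$reject_uv)
        rej <- st$epochs$rejected
        write.table(rej[!is.na(rej$reason), ], out("rejection_log.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        log_line(stage, "info", "epoched",
                 trials = nrow(rej), rejected = sum(!is.na(rej$reason)))
        finish(stage, out("rejection_log.tsv"), t0)
      },
      features = {
        files <- c(out("features.tsv"), out("features.tsv.columns.tsv"))
        if (outputs_current(manifest, cfg_hash, stage, files)) {
          st$features <- read_features_tsv(out("features.tsv"))
          finish(stage, files, t0, skipped = TRUE)
        } else {
          epochs <- need("epochs", "preprocess")
          st$features <- build_feature_matrix(epochs, p,
                                              pe_step = config$pe_step)
          write_features_tsv(st$features, out("features.tsv"))
          finish(stage, files, t0)
        }
      },
      cluster = {
        fm <- zscore_features(need("features", "features"))
        st$features_z <- fm
        sol <- consensus_kmeans(fm, config$k, config$runs,
                                derive_seed(config$seed, "cluster"))
        st$solution <- sol
        lab <- data.frame(fm$events, consensus = sol$consensus_labels,
                          vote_fraction = sol$vote_fraction)
        write.table(lab, out("labels.tsv"), sep = "\t", row.names = FALSE,
                    quote = FALSE)
        qr <- quality_report(fm, sol)
        st$quality <- qr
        jsonlite::write_json(list(
          k = sol$k, dbi = qr$dbi, silhouette = qr$silhouette_mean,
          dunn = qr$dunn, median_run_ari = median(qr$ari_to_reference),
          vote_fraction_median = qr$vote_fraction_median),
          out("quality.json"), auto_unbox = TRUE, digits = NA)
        finish(stage, c(out("labels.tsv"), out("quality.json")), t0)
      },
      validate_k = {
        fm <- st$features_z %||% zscore_features(need("features", "features"))
        br <- bootstrap_k(fm, config$k_grid, config$n_boot, config$runs,
                          derive_seed(config$seed, "validate_k"))
        st$bootstrap <- br
        write.table(br$per_replicate, out("bootstrap.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        jsonlite::write_json(list(selected_k = br$selected_k,
                                  summary = br$summary, paired = br$paired,
                                  n_flagged = br$n_flagged),
                             out("bootstrap.json"), auto_unbox = TRUE,
                             digits = NA)
        finish(stage, c(out("bootstrap.tsv"), out("bootstrap.json")), t0)
      },
      loo = {
        fm <- need("features", "features")
        lv <- loo_validate(fm, config$k, config$runs,
                           derive_seed(config$seed, "loo"))
        st$loo <- lv
        write.table(lv$per_subject, out("loo.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        finish(stage, out("loo.tsv"), t0)
      },
      infoshare = {
        fm <- st$features_z %||% zscore_features(need("features", "features"))
        embs <- list(spectra = family_pca(fm, "spectra"),
                     pe = family_pca(fm, "pe"),
                     pcmi = family_pca(fm, "pcmi"))
        sm <- sharing_matrix(embs, k = config$ksg_k)
        st$sharing <- sm
        write.table(sharing_long(sm), out("sharing.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        jsonlite::write_json(list(R = as.data.frame(sm$R),
                                  I_self = as.list(sm$I_self),
                                  n_clamped = sm$n_clamped),
                             out("sharing.json"), auto_unbox = TRUE,
                             digits = NA)
        finish(stage, c(out("sharing.tsv"), out("sharing.json")), t0)
      },
      report = {
        sol <- st$solution
        if (is.null(sol)) stop_bad_arg("report needs the cluster stage")
        fm <- st$features_z
        rep <- list(k = sol$k,
                    cluster_sizes = as.list(table(sol$consensus_labels)),
                    vote_fraction_median = median(sol$vote_fraction))
        if ("true_state" %in% colnames(fm$events)) {
          comp <- table(cluster = sol$consensus_labels,
                        state = fm$events$true_state)
          rep$state_composition <- as.data.frame.matrix(comp)
          rep$ari_vs_truth <- adjusted_rand(sol$consensus_labels,
                                            fm$events$true_state)
        }
        if (!is.null(st$bootstrap)) {
          rep$bootstrap_selected_k <- st$bootstrap$selected_k
          if (st$bootstrap$selected_k != sol$k)
            log_line(stage, "warn", "bootstrap prefers a different k",
                     bootstrap_k = st$bootstrap$selected_k, used_k = sol$k)
        }
        if (!is.null(st$sharing)) rep$R <- as.data.frame(st$sharing$R)
        if (!is.null(st$quality))
          rep$quality <- list(dbi = st$quality$dbi,
                              silhouette = st$quality$silhouette_mean,
                              dunn = st$quality$dunn)
        jsonlite::write_json(rep, out("report.json"), auto_unbox = TRUE,
                             digits = NA)
        txt <- c(sprintf("nocistate run: %d clusters", sol$k),
                 capture.output(print(table(sol$consensus_labels))),
                 if (!is.null(rep$state_composition))
                   c("cluster x state composition:",
                     capture.output(print(rep$state_composition))))
        writeLines(txt, out("report.txt"))
        finish(stage, c(out("report.json"), out("report.txt")), t0)
      },
      stop_bad_arg(paste("unknown stage:", stage)))
  }
  jsonlite::write_json(new_manifest, manifest_path(config$out_dir),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = st$cohort, epochs = st$epochs,
                 features = st$features, solution = st$solution,
                 bootstrap = st$bootstrap, loo = st$loo,
                 sharing = st$sharing, manifest = new_manifest))
}
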