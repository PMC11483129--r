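#' Pipeline configuration
#'
#' All parameters and seeds of an end-to-end synthetic run, serializable to
#' YAML. Defaults describe the demonstration study: a 32-subject cohort with
#' a planted rho = -0.6 association between ROI U-fiber amplitude and
#' auditory asynchrony, on a one-hemisphere sphere phantom.
#'
#' @param ... overrides of the default fields (nested lists `phantom`,
#'   `cohort`, `sampling`, `stats`, `rcca`)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    phantom = list(outer_radius = 20, inner_radius = 10, voxel_size = 1,
                   gyrification_amplitude = 0, mesh_order = 3,
                   hemispheres = 1, n_roi = 8, seed = 1),
    cohort = list(n_subjects = 32, rho_planted = -0.6, roi_id = 3,
                  seed = 42, trials_per_interval = 10),
    sampling = list(depths = c(0, 0.5, 1, 1.5, 2), analysis_depth = 1.5,
                    angle_cutoff = 45, smoothing_fwhm = 4),
    laplace = list(tol = 1e-6, max_iter = 10000, omega = 1.9),
    trace = list(step = 0.1, max_length = 5),
    stats = list(metric = "mean_abs_asynchrony", modality = "auditory",
                 target_ms = 650, p_cft = 0.001, n_perm = 1999,
                 alpha_cluster = 0.001, seed = 7),
    rcca = list(lambda_grid = 10^seq(-2, 1, length.out = 3), k_folds = 4,
                n_perm = 500, level = 0.99, seed = 11)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && nm %in% names(cfg)) {
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else {
      cfg[[nm]] <- ov[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param config a [pipeline_config()]
#' @param path YAML path
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full synthetic pipeline
#'
#' Executes phantom generation, cohort simulation, the Laplace field,
#' streamline tracing, depth-resolved AFD sampling with surface smoothing,
#' behavioral summaries, the vertex-wise correlation with permutation
#' cluster correction, ROI aggregation, and the regularized CCA, writing
#' every intermediate artifact plus a JSON manifest (parameters, seeds, file
#' hashes) and a log to `out_dir`. Re-running with the same configuration
#' reproduces identical outputs.
#'
#' @param config a [pipeline_config()]
#' @param out_dir writable output directory
#' @return the run manifest (list), invisibly; the manifest is also written
#'   as `manifest.json`
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%H:%M:%S"), msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  manifest <- list(package_version = as.character(utils::packageVersion("ufiber")),
                   config = unclass(config), stages = list())
  files <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      write_manifest()
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }
  write_manifest <- function() {
    manifest$file_hashes <- as.list(tools::md5sum(files[file.exists(files)]))
    names(manifest$file_hashes) <- basename(names(manifest$file_hashes))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  say("phantom: building geometry")
  ph <- stage("phantom", do.call(make_phantom, config$phantom))
  files <- c(files,
             write_volume_nifti(ph$wm_mask, file.path(out_dir, "wm_mask.nii.gz"),
                                ph$origin, ph$voxel_size, "int8"),
             write_volume_nifti(ph$ventricle_mask, file.path(out_dir, "ventricle_mask.nii.gz"),
                                ph$origin, ph$voxel_size, "int8"),
             write_surface_txt(ph$surface, file.path(out_dir, "surface.txt")))
  utils::write.csv(data.frame(vertex_id = seq_along(ph$roi_labels),
                              roi = ph$roi_labels),
                   file.path(out_dir, "roi_labels.csv"), row.names = FALSE)
  files <- c(files, file.path(out_dir, "roi_labels.csv"))
  say("phantom: %d vertices, %d wm voxels", nrow(ph$surface$vertices), sum(ph$wm_mask))

  say("cohort: simulating %d subjects", config$cohort$n_subjects)
  co <- stage("cohort", generate_cohort(
    n_subjects = config$cohort$n_subjects,
    rho_planted = config$cohort$rho_planted,
    roi_id = config$cohort$roi_id, seed = config$cohort$seed,
    phantom = ph, make_fields = FALSE,
    trials_per_interval = config$cohort$trials_per_interval))
  files <- c(files, write_events_csv(
    unlist(lapply(co$sessions, unname), recursive = FALSE),
    file.path(out_dir, "events.csv")))

  say("behavior: summarizing tapping sessions")
  summaries <- stage("behavior", do.call(rbind, lapply(co$sessions, function(s)
    rbind(summarize_subject(s$auditory), summarize_subject(s$visual)))))
  utils::write.csv(summaries, file.path(out_dir, "behavior.csv"), row.names = FALSE)
  files <- c(files, file.path(out_dir, "behavior.csv"))

  say("laplace: solving potential field")
  fld <- stage("laplace", solve_laplace(ph, tol = config$laplace$tol,
                                        max_iter = config$laplace$max_iter,
                                        omega = config$laplace$omega))
  say("laplace: %d sweeps, residual %.2e", fld$iterations, fld$residual)
  phi_out <- fld$phi; phi_out[is.na(phi_out)] <- 0
  files <- c(files, write_volume_nifti(phi_out, file.path(out_dir, "phi.nii.gz"),
                                       ph$origin, ph$voxel_size, "float32"))
  grad <- gradient_field(fld)

  say("trace: %d streamlines", nrow(ph$surface$vertices))
  sl <- stage("trace", trace_streamlines(ph, grad, step = config$trace$step,
                                         max_length = config$trace$max_length))
  files <- c(files, write_streamlines_tck(sl, file.path(out_dir, "streamlines.tck.txt")))

  say("sampling: depth profiles for %d subjects", config$cohort$n_subjects)
  depths <- config$sampling$depths
  nd <- length(depths); nv <- nrow(ph$surface$vertices)
  n <- config$cohort$n_subjects
  samp <- stage("sampling", {
    arr <- array(NA_real_, c(n, nv, nd, 3))
    for (i in seq_len(n)) {
      ffi <- plant_fixel_field(ph, subject = co$truth$subject_specs[[i]],
                               roi_id = co$truth$roi_id)
      ds <- sample_depth_profiles(ffi, sl, depths,
                                  angle_cutoff = config$sampling$angle_cutoff)
      for (mkt in 1:3) {
        for (j in seq_len(nd)) {
          arr[i, , j, mkt] <- smooth_surface_metric(
            ph$surface, ds[, j, mkt], fwhm = config$sampling$smoothing_fwhm)
        }
      }
    }
    dimnames(arr) <- list(NULL, NULL, paste0(depths, "mm"), c("total", "par", "tan"))
    arr
  })
  di <- which.min(abs(depths - config$sampling$analysis_depth))
  long <- data.frame(subject = rep(seq_len(n), nv),
                     vertex_id = rep(seq_len(nv), each = n),
                     total = fmt_num(as.vector(samp[, , di, "total"])),
                     par = fmt_num(as.vector(samp[, , di, "par"])),
                     tan = fmt_num(as.vector(samp[, , di, "tan"])))
  utils::write.csv(long, file.path(out_dir, "afd_analysis_depth.csv"),
                   row.names = FALSE, quote = FALSE)
  files <- c(files, file.path(out_dir, "afd_analysis_depth.csv"))

  say("stats: vertex-wise correlation + cluster correction (depth %.1f mm)",
      depths[di])
  beh <- summaries[summaries$modality == config$stats$modality &
                   summaries$target_ms == config$stats$target_ms,
                   config$stats$metric]
  vs <- stage("stats", {
    v <- vertexwise_correlation(samp[, , di, "tan"], beh,
                                depth_mm = depths[di], metric = "tan")
    cluster_correction(v, ph$surface, p_cft = config$stats$p_cft,
                       n_perm = config$stats$n_perm,
                       alpha_cluster = config$stats$alpha_cluster,
                       seed = config$stats$seed)
  })
  rmap <- data.frame(vertex_id = seq_len(nv), r = fmt_num(vs$r_map),
                     r2 = fmt_num(vs$r2_map), p = fmt_num(vs$p_map))
  utils::write.csv(rmap, file.path(out_dir, "vertex_stats.csv"),
                   row.names = FALSE, quote = FALSE)
  ctab <- if (length(vs$clusters)) {
    do.call(rbind, lapply(seq_along(vs$clusters), function(k) {
      cl <- vs$clusters[[k]]
      data.frame(cluster_id = k, n_vertices = cl$size,
                 p_cluster = cl$p_cluster, peak_vertex = cl$peak_vertex,
                 mean_r = cl$mean_r, significant = cl$significant)
    }))
  } else data.frame(cluster_id = integer(0), n_vertices = integer(0),
                    p_cluster = numeric(0), peak_vertex = integer(0),
                    mean_r = numeric(0), significant = logical(0))
  utils::write.csv(ctab, file.path(out_dir, "clusters.csv"), row.names = FALSE)
  roi <- roi_aggregate(vs, ph$roi_labels)
  utils::write.csv(roi, file.path(out_dir, "roi_summary.csv"), row.names = FALSE)
  files <- c(files, file.path(out_dir, c("vertex_stats.csv", "clusters.csv",
                                         "roi_summary.csv")))
  say("stats: %d clusters, %d significant", length(vs$clusters),
      sum(vapply(vs$clusters, `[[`, logical(1), "significant")))

  say("rcca: grid search + permutation CIs")
  rc <- stage("rcca", {
    X <- behavior_matrix(summaries)
    Y <- samp[, , di, "tan"]
    keep <- apply(Y, 2, function(cc) !anyNA(cc) && stats::sd(cc) > 0)
    lv <- config$rcca$lambda_grid
    gs <- grid_search_lambdas(X, Y[, keep, drop = FALSE],
                              grid = expand.grid(lambda_x = lv, lambda_y = lv),
                              k_folds = config$rcca$k_folds,
                              seed = config$rcca$seed)
    fit <- permutation_loading_cis(gs$fit, X, Y[, keep, drop = FALSE],
                                   n_perm = config$rcca$n_perm,
                                   level = config$rcca$level,
                                   seed = config$rcca$seed + 1)
    list(fit = fit, gs = gs, keep = which(keep))
  })
  utils::write.csv(cbind(rc$fit$ci99$x,
                         row_type = "behavior"),
                   file.path(out_dir, "rcca_loadings_behavior.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(subject = seq_len(n), U = fmt_num(rc$fit$U),
                              V = fmt_num(rc$fit$V)),
                   file.path(out_dir, "rcca_variates.csv"),
                   row.names = FALSE, quote = FALSE)
  files <- c(files, file.path(out_dir, c("rcca_loadings_behavior.csv",
                                         "rcca_variates.csv")))
  say("rcca: lambda = (%g, %g), canonical corr %.3f, cv corr %.3f",
      rc$fit$lambda_x, rc$fit$lambda_y, rc$fit$canonical_corr, rc$gs$cv_corr)

  manifest$counts <- list(vertices = nv, wm_voxels = sum(ph$wm_mask),
                          subjects = n,
                          clusters = length(vs$clusters),
                          significant_clusters =
                            sum(vapply(vs$clusters, `[[`, logical(1), "significant")))
  write_manifest()
  say("done")
  invisible(manifest)
}

#' Wide behavioral matrix for the rCCA
#'
#' One row per subject, one column per (modality, target, metric)
#' combination, named `<modality>_<target>_<metric>`.
#'
#' @param summaries rbind-ed [summarize_subject()] rows for a cohort
#' @param metrics which summary columns to spread
#' @return numeric matrix with subjects in row order of first appearance
#' @export
behavior_matrix <- function(summaries,
                            metrics = c("mean_abs_asynchrony",
                                        "constant_error_sync",
                                        "temporal_variability_sync",
                                        "lag1_autocorr")) {
  subs <- unique(summaries$subject_id)
  cols <- list()
  for (mod in unique(summaries$modality)) {
    for (tg in sort(unique(summaries$target_ms))) {
      for (mt in metrics) {
        sel <- summaries$modality == mod & summaries$target_ms == tg
        v <- summaries[[mt]][sel][match(subs, summaries$subject_id[sel])]
        cols[[paste(mod, tg, mt, sep = "_")]] <- v
      }
    }
  }
  do.call(cbind, cols)
}

#' Verify read/write round trips of every supported format
#'
#' Writes a small phantom's masks (NIfTI), surface (text), a fixel
#' directory, a streamline file and an event CSV into `path`, reads each
#' back, and checks payload equality; used as a self-test of the I/O layer.
#'
#' @param path scratch directory
#' @return TRUE invisibly; stops with a message on the first mismatch
#' @export
read_write_roundtrips <- function(path = tempfile("ufiber_io_")) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ph <- make_phantom(10, 5, 1, mesh_order = 1)
  chk <- function(ok, what) if (!isTRUE(ok)) stop("round trip failed: ", what)

  p <- file.path(path, "wm.nii.gz")
  write_volume_nifti(ph$wm_mask, p, ph$origin, ph$voxel_size, "int8")
  rt <- read_volume_nifti(p)
  chk(identical(rt$data == 1, ph$wm_mask), "nifti mask payload")
  chk(max(abs(rt$origin - ph$origin)) < 1e-6, "nifti affine")

  ps <- file.path(path, "surf.txt")
  write_surface_txt(ph$surface, ps)
  s2 <- read_surface_txt(ps)
  chk(identical(s2$vertices, ph$surface$vertices), "surface vertices")
  chk(identical(s2$faces, ph$surface$faces), "surface faces")

  ff <- plant_fixel_field(ph, subject = subject_spec(seed = 5), roi_id = 2)
  fd <- file.path(path, "fixels")
  write_fixel_dir(ff, fd)
  f2 <- read_fixel_dir(fd)
  chk(identical(f2$vox, ff$vox) && identical(f2$afd, ff$afd) &&
        identical(f2$dir, ff$dir) && identical(f2$count, ff$count),
      "fixel directory")

  fl <- solve_laplace(ph)
  sl <- trace_streamlines(ph, gradient_field(fl))
  pt <- file.path(path, "sl.tck.txt")
  write_streamlines_tck(sl, pt)
  r <- read_streamlines_tck(pt)
  i <- which.max(sl$n_points)
  chk(identical(r$streamlines[[i]],
                sl$points[seq_len(sl$n_points[i]), , i, drop = FALSE][, , 1, drop = TRUE]),
      "streamline points")

  sess <- simulate_tapping_session(subject_spec(seed = 2), "auditory",
                                   target_intervals = c(650, 750),
                                   trials_per_interval = 2)
  pe <- file.path(path, "events.csv")
  write_events_csv(sess, pe)
  e2 <- read_events_csv(pe)[[1]]
  chk(identical(e2$events$onset_ms, sess$events$onset_ms), "event onsets")
  invisible(TRUE)
}
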