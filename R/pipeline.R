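#' Pipeline configuration
#'
#' One flat configuration object for the per-subject pipeline
#' (resample -> register -> extract -> measure) and the cohort analysis.
#' Serializable to/from YAML; every cohort report embeds the configuration
#' hash for provenance.
#'
#' @param target_spacing_mm working voxel size volumes are resampled to.
#' @param register run cranial-base MI registration (TRUE) or assume the
#'   scans are already in one frame.
#' @param reg_control a [reg_control()].
#' @param direction `"t1-to-t2"` (regions painted on the baseline mesh,
#'   queries against the registered follow-up) or `"t2-to-t1"`.
#' @param regions region definition tibble (`name`, `label`, `seed_x/y/z`,
#'   `radius_mm`, `metric`); default the standard phantom areas.
#' @param mesh_labels label names to extract surfaces for.
#' @param antialias_sigma passed to [extract_surface()].
#' @param alpha significance level for the correlation matrices.
#' @param session2_jitter_mm sd of the tangential seed-point jitter used to
#'   emulate the operator re-painting areas in the repeat session
#'   (0 = duplicate sessions).
#' @param seed RNG seed for the re-measurement jitter.
#' @return A list of class `dq_config`.
#' @export
pipeline_config <- function(target_spacing_mm = 0.5,
                            register = TRUE,
                            reg_control = dispquant::reg_control(),
                            direction = c("t1-to-t2", "t2-to-t1"),
                            regions = NULL,
                            mesh_labels = c("maxilla_upper_teeth",
                                            "mandible_lower_teeth",
                                            "soft_tissue"),
                            antialias_sigma = 1,
                            alpha = 0.05,
                            session2_jitter_mm = 0.3,
                            seed = 1L) {
  direction <- match.arg(direction)
  structure(list(target_spacing_mm = as.numeric(target_spacing_mm),
                 register = isTRUE(register),
                 reg_control = reg_control, direction = direction,
                 regions = regions,
                 mesh_labels = as.character(mesh_labels),
                 antialias_sigma = as.numeric(antialias_sigma),
                 alpha = as.numeric(alpha),
                 session2_jitter_mm = as.numeric(session2_jitter_mm),
                 seed = as.integer(seed)),
            class = "dq_config")
}

config_hash <- function(config) {
  digest::digest(unclass(config), algo = "xxhash64")
}

#' Read / write pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  c2 <- unclass(config)
  c2$reg_control <- unclass(c2$reg_control)
  if (!is.null(c2$regions)) c2$regions <- as.data.frame(c2$regions)
  yaml::write_yaml(c2, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  if (!is.null(args$reg_control))
    args$reg_control <- do.call(reg_control, args$reg_control)
  if (!is.null(args$regions))
    args$regions <- tibble::as_tibble(as.data.frame(args$regions))
  do.call(pipeline_config, args)
}

subject_regions <- function(subject, config) {
  if (!is.null(config$regions)) return(tibble::as_tibble(config$regions))
  spec <- attr(subject$labels_t1, "phantom_spec")
  if (is.null(spec))
    stop("no region definitions in the config and the subject is not a phantom")
  phantom_default_regions(spec)
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  message(sprintf("  stage %-10s %6.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the measurement pipeline for one subject
#'
#' Full per-subject protocol: resample both scans to the working spacing,
#' recover the cranial-base rigid superimposition (T1 is always the
#' reference frame), extract per-label surfaces at both time points, map the
#' follow-up meshes into the reference frame, paint the configured regions
#' and measure signed closest-point displacement summaries. Any stage
#' failure aborts the subject with an error naming the stage.
#'
#' @param subject a cohort subject (list with `volume_t1`, `labels_t1`,
#'   `volume_t2`, `labels_t2`, optional `id`), e.g. from [make_cohort()].
#' @param config a [pipeline_config()].
#' @param seed_jitter optional n_regions x 2 matrix of tangential (x, z)
#'   seed offsets, mm — used by [run_cohort()] to emulate the repeat
#'   measurement session.
#' @return Tibble of region summaries (one row per region) with the subject
#'   id; the recovered transform, the meshes and the configuration hash are
#'   attached as attributes.
#' @export
prepare_subject <- function(subject, config) {
  regions <- stage("regions", subject_regions(subject, config))
  v1 <- subject$volume_t1; v2 <- subject$volume_t2
  l1 <- subject$labels_t1; l2 <- subject$labels_t2
  if (!isTRUE(all.equal(v1$spacing_mm,
                        rep(config$target_spacing_mm, 3)))) {
    v1 <- stage("resample", resample(v1, config$target_spacing_mm))
    l1 <- resample(l1, config$target_spacing_mm)
  }
  if (!isTRUE(all.equal(v2$spacing_mm,
                        rep(config$target_spacing_mm, 3)))) {
    v2 <- stage("resample", resample(v2, config$target_spacing_mm))
    l2 <- resample(l2, config$target_spacing_mm)
  }
  tfm <- if (config$register) {
    stage("register", register_rigid(v1, v2, l1, config$reg_control))
  } else rigid_transform()
  needed <- unique(regions$label)
  meshes1 <- meshes2 <- list()
  for (lb in needed) {
    meshes1[[lb]] <- stage("extract",
                           extract_surface(l1, lb, config$antialias_sigma))
    m2 <- stage("extract", extract_surface(l2, lb, config$antialias_sigma))
    meshes2[[lb]] <- if (config$register) apply_transform(m2, tfm) else m2
  }
  list(regions = regions, meshes1 = meshes1, meshes2 = meshes2,
       transform = tfm,
       id = if (!is.null(subject$id)) subject$id else "S01")
}

measure_prepared <- function(prep, config, seed_jitter = NULL) {
  flip <- config$direction == "t2-to-t1"
  regions <- prep$regions
  out <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    src <- if (flip) prep$meshes2[[r$label]] else prep$meshes1[[r$label]]
    tgt <- if (flip) prep$meshes1[[r$label]] else prep$meshes2[[r$label]]
    seed <- c(r$seed_x, r$seed_y, r$seed_z)
    if (!is.null(seed_jitter)) seed <- seed + c(seed_jitter[i, 1], 0,
                                                seed_jitter[i, 2])
    if (flip) {
      near <- which.min(colSums((t(src$vertices) - seed)^2))
      seed <- src$vertices[near, ]
    }
    reg <- paint_region(src, seed, r$radius_mm, r$metric, name = r$name)
    # in the flipped direction the geometric sign is reversed relative to
    # the T1 -> T2 anatomical change; reports keep advancement positive
    suppressWarnings(region_summary(reg, src, tgt, negate = flip))
  })
  out <- dplyr::mutate(out, subject = prep$id, .before = 1)
  attr(out, "transform") <- prep$transform
  attr(out, "direction") <- config$direction
  attr(out, "config_hash") <- config_hash(config)
  out
}

run_subject <- function(subject, config = pipeline_config(),
                        seed_jitter = NULL) {
  prep <- prepare_subject(subject, config)
  measure_prepared(prep, config, seed_jitter)
}

#' Run the full cohort analysis
#'
#' Runs [run_subject()] for every subject (continuing past per-subject
#' failures and tallying them), measures every area twice — the second
#' session with small tangential seed-point jitter emulating the operator
#' re-painting the areas — and produces the four study-style outputs:
#' the repeatability table (ICC + between-session differences), the
#' descriptive displacement table, and the maxillary and mandibular
#' Spearman correlation matrices.
#'
#' @param cohort a [make_cohort()] object, or a list of subjects.
#' @param config a [pipeline_config()].
#' @return Object of class `dq_cohort_report`: `measurements`,
#'   `measurements_repeat`, `repeatability`, `descriptives`,
#'   `cor_maxillary`, `cor_mandibular`, `failures`, `config_hash`.
#' @export
run_cohort <- function(cohort, config = pipeline_config()) {
  subjects <- if (inherits(cohort, "dq_cohort")) cohort$subjects else cohort
  if (length(subjects) < 3)
    stop("cohort correlations need at least 3 subjects")
  rows1 <- list(); rows2 <- list(); failures <- character(0)
  for (j in seq_along(subjects)) {
    s <- subjects[[j]]
    res <- tryCatch({
      prep <- prepare_subject(s, config)
      r1 <- measure_prepared(prep, config)
      nreg <- nrow(r1)
      jit <- if (config$session2_jitter_mm > 0)
        with_seed(config$seed + j,
                  matrix(stats::rnorm(2 * nreg, 0, config$session2_jitter_mm),
                         ncol = 2))
      else NULL
      r2 <- if (is.null(jit)) r1
            else measure_prepared(prep, config, seed_jitter = jit)
      list(r1 = r1, r2 = r2)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s",
                                      if (!is.null(s$id)) s$id else j,
                                      conditionMessage(res)))
    } else {
      rows1[[length(rows1) + 1]] <- res$r1
      rows2[[length(rows2) + 1]] <- res$r2
    }
  }
  if (length(rows1) < 3)
    stop("fewer than 3 subjects measured successfully; failures:\n",
         paste(failures, collapse = "\n"))
  to_table <- function(rows) {
    long <- dplyr::bind_rows(rows)
    wide <- tidyr::pivot_wider(long[, c("subject", "region", "mean_mm")],
                               names_from = "region", values_from = "mean_mm")
    as_measurement_table(wide)
  }
  m1 <- to_table(rows1); m2 <- to_table(rows2)
  areas <- measurement_areas(m1)
  cor_for <- function(set) {
    want <- intersect(area_set(set), areas)
    if (length(want) < 2) return(NULL)
    correlation_matrix(m1, want, alpha = config$alpha)
  }
  out <- list(measurements = m1, measurements_repeat = m2,
              repeatability = difference_report(m1, m2),
              descriptives = descriptives(m1),
              cor_maxillary = cor_for("maxillary"),
              cor_mandibular = cor_for("mandibular"),
              failures = failures,
              config_hash = config_hash(config))
  class(out) <- "dq_cohort_report"
  out
}

#' @export
print.dq_cohort_report <- function(x, ...) {
  cat("== Repeatability (ICC and between-session differences, mm) ==\n")
  print(as.data.frame(x$repeatability), digits = 3)
  cat("\n== Descriptive statistics of displacement (mm) ==\n")
  print(as.data.frame(x$descriptives), digits = 3)
  if (!is.null(x$cor_maxillary)) {
    cat("\n== Maxillary areas ==\n"); print(x$cor_maxillary)
  }
  if (!is.null(x$cor_mandibular)) {
    cat("\n== Mandibular areas ==\n"); print(x$cor_mandibular)
  }
  if (length(x$failures))
    cat("\nFailed subjects:\n", paste(" ", x$failures, collapse = "\n"), "\n")
  invisible(x)
}

#' Write measurement and report tables as CSV
#'
#' @param report a `dq_cohort_report`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report_csv <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$measurements,
                   file.path(dir, "measurements_session1.csv"), row.names = FALSE)
  utils::write.csv(report$measurements_repeat,
                   file.path(dir, "measurements_session2.csv"), row.names = FALSE)
  utils::write.csv(report$repeatability,
                   file.path(dir, "repeatability.csv"), row.names = FALSE)
  utils::write.csv(report$descriptives,
                   file.path(dir, "descriptives.csv"), row.names = FALSE)
  for (nm in c("cor_maxillary", "cor_mandibular")) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(report[[nm]]$r, file.path(dir, paste0(nm, "_r.csv")))
      utils::write.csv(report[[nm]]$p, file.path(dir, paste0(nm, "_p.csv")))
    }
  }
  invisible(dir)
}
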