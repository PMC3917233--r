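#' Pipeline run configuration
#'
#' Collects every stage parameter of an end-to-end run. Defaults mirror the
#' package defaults of the individual stage functions; a config round-trips
#' losslessly through YAML and the resolved copy is written next to each
#' run's outputs.
#'
#' @param sections list of section inputs; each entry a list with either
#'   `spec` (a [section_spec()] or its argument list) for synthetic input,
#'   plus `genotype` and `timepoint`.
#' @param seed global seed.
#' @param gamma,contrast,brightness preprocessing parameters.
#' @param window_px,offset adaptive binarization parameters.
#' @param n_erosions,n_dilations,selem_size morphological clean-up.
#' @param tolerance,min_cell_px watershed parameters.
#' @param qc_direction xylem-correction policy (see [correct_xylem()]).
#' @param classify whether to run cell-type classification and QC; defaults
#'   to `TRUE` when `train_sections` or a registry entry is available.
#' @param classifier_registry named list mapping `genotype_timepoint` keys
#'   to saved classifier directories (see [save_classifier()]); consulted
#'   when no training sections are configured.
#' @param train_sections indices of `sections` whose ground-truth labels
#'   train the classifier (synthetic runs); `NULL` disables training.
#' @param classifier_features features for the classifier; `NULL` runs
#'   greedy selection.
#' @param lowess_frac,dip_n_boot morphodynamics parameters.
#' @param poles list with `enabled`, `width`, `blur_sigma` for ring-profile
#'   analysis of synthetic reporter rings.
#' @return list of class `run_config`.
#' @export
run_config <- function(sections, seed = 1L, gamma = 1, contrast = 1,
                       brightness = 0, window_px = 31L, offset = 10,
                       n_erosions = 1L, n_dilations = 1L, selem_size = 3L,
                       tolerance = 2, min_cell_px = 20L,
                       qc_direction = "both", classify = NULL,
                       classifier_registry = list(), train_sections = NULL,
                       classifier_features = c("area", "polar_radius_norm"),
                       lowess_frac = 0.3, dip_n_boot = 500L,
                       poles = list(enabled = FALSE, width = 5, blur_sigma = 2)) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as YAML
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `read_run_config` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  # named atomic vectors must become maps, or YAML drops their names
  yamlify <- function(x) {
    if (is.list(x)) {
      lapply(x, yamlify)
    } else if (is.atomic(x) && !is.null(names(x)) && length(x) > 1) {
      as.list(x)
    } else {
      x
    }
  }
  yaml::write_yaml(yamlify(unclass(config)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "run_config"
  cfg
}

.stage <- function(name, log_con, expr) {
  line <- function(status, extra = "") {
    msg <- sprintf("[%s] stage=%s %s", format(Sys.time(), "%H:%M:%S"), name, paste(status, extra))
    writeLines(msg, log_con)
  }
  line("start")
  out <- tryCatch(expr, error = function(e) {
    line("FAIL", conditionMessage(e))
    stop(sprintf("stage %s failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
  line("ok")
  out
}

#' Run the full pipeline on a configuration
#'
#' Executes generate/stitch, preprocess, binarize, clean, watershed,
#' feature extraction, (optional) classification, QC and the section-level
#' analyses, writing every artifact into a write-once run directory:
#' `images/`, `labels/`, `tables/`, `models/`, `reports/`, the resolved
#' config and a structured `run.log` with output checksums. Reruns with the
#' same config and seed are bit-identical for the deterministic stages.
#'
#' @param config a `run_config`.
#' @param out_dir run directory (created; must not contain a previous run).
#' @return invisibly, a list with the per-section feature tables and the
#'   paths of the written artifacts.
#' @export
run_pipeline <- function(config, out_dir) {
  .assert(inherits(config, "run_config"), "config must be a run_config")
  .assert(length(config$sections) >= 1, "config has no sections")
  if (dir.exists(file.path(out_dir, "tables"))) {
    stop("out_dir already holds a run (write-once)", call. = FALSE)
  }
  for (d in c("images", "labels", "tables", "models", "reports")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  write_run_config(config, file.path(out_dir, "config.resolved.yaml"))
  log_con <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(log_con))

  n_sec <- length(config$sections)
  tables <- vector("list", n_sec)
  truths <- vector("list", n_sec)
  keys <- character(n_sec)
  for (i in seq_len(n_sec)) {
    sec_cfg <- config$sections[[i]]
    keys[i] <- paste0(sec_cfg$genotype, "_", sec_cfg$timepoint)
    nm <- sprintf("section%02d_%s", i, keys[i])
    gen <- .stage(paste0("generate:", nm), log_con, {
      spec <- sec_cfg$spec
      if (!inherits(spec, "section_spec")) spec <- do.call(section_spec, spec)
      generate_section(spec)
    })
    truths[[i]] <- gen$truth
    img <- .stage(paste0("preprocess:", nm), log_con, {
      preprocess(gen$image, config$gamma, config$contrast, config$brightness)
    })
    labels <- .stage(paste0("segment:", nm), log_con, {
      wall <- binarize_adaptive(img, config$window_px, config$offset)
      wall <- morph_clean(wall, config$n_erosions, config$n_dilations, config$selem_size)
      watershed_segment(img, wall, config$tolerance, config$min_cell_px)
    })
    ft <- .stage(paste0("features:", nm), log_con, {
      build_feature_table(labels, gen$image$center, gen$image$pixel_size,
        genotype = sec_cfg$genotype, timepoint = sec_cfg$timepoint
      )
    })
    .stage(paste0("write:", nm), log_con, {
      tiff::writeTIFF(
        labels$labels / 65535,
        file.path(out_dir, "labels", paste0(nm, ".tif")),
        bits.per.sample = 16L
      )
      tiff::writeTIFF(
        gen$image$pixels / 255,
        file.path(out_dir, "images", paste0(nm, ".tif")),
        bits.per.sample = 8L
      )
      write_mask(gen$masks$section, file.path(out_dir, "images", paste0(nm, "_section_mask.png")))
      write_mask(gen$masks$xylem, file.path(out_dir, "images", paste0(nm, "_xylem_mask.png")))
    })
    attr(ft, "masks") <- gen$masks
    tables[[i]] <- ft
  }

  do_classify <- if (is.null(config$classify)) {
    !is.null(config$train_sections) || length(config$classifier_registry) > 0
  } else {
    isTRUE(config$classify)
  }
  clf <- NULL
  if (!is.null(config$train_sections)) {
    clf <- .stage("train", log_con, {
      train_rows <- lapply(config$train_sections, function(i) {
        .label_from_truth(tables[[i]], truths[[i]])
      })
      train <- do.call(rbind, train_rows)
      feats <- config$classifier_features
      if (is.null(feats)) {
        feats <- greedy_feature_selection(train, max_k = 6, seed = config$seed)$selected
      }
      train_classifier(train, feats, seed = config$seed)
    })
    save_classifier(clf, file.path(out_dir, "models", "classifier"))
  }
  if (do_classify) {
    for (i in seq_len(n_sec)) {
      clf_i <- clf
      if (is.null(clf_i)) {
        reg <- config$classifier_registry[[keys[i]]]
        if (is.null(reg)) {
          stop(sprintf(
            "no classifier for (genotype, timepoint) key: %s", keys[i]
          ), call. = FALSE)
        }
        clf_i <- load_classifier(reg)
      }
      tables[[i]] <- .stage(paste0("classify:section", i), log_con, {
        predict_classes(clf_i, tables[[i]])
      })
      tables[[i]] <- .stage(paste0("qc:section", i), log_con, {
        masks <- attr(tables[[i]], "masks")
        flt <- filter_outside(tables[[i]], masks)
        cor <- correct_xylem(flt$kept, masks, config$qc_direction)
        utils::write.csv(cor$changes,
          file.path(out_dir, "reports", sprintf("qc_changes_section%02d.csv", i)),
          row.names = FALSE
        )
        out <- cor$table
        attr(out, "masks") <- masks
        out
      })
    }
  }

  for (i in seq_len(n_sec)) {
    write_feature_table(
      tables[[i]],
      file.path(out_dir, "tables", sprintf("features_section%02d.csv", i))
    )
  }

  if (do_classify) {
    .stage("phenotype", log_con, {
      by_key <- split(seq_len(n_sec), keys)
      pps <- lapply(names(by_key), function(k) {
        idx <- by_key[[k]]
        compute_phenoprint(
          tables[idx],
          genotype = config$sections[[idx[1]]]$genotype,
          timepoint = config$sections[[idx[1]]]$timepoint
        )
      })
      m <- phenoprint_matrix(pps)
      utils::write.csv(as.data.frame(m),
        file.path(out_dir, "reports", "phenoprints.csv"),
        row.names = TRUE
      )
    })
  }

  .stage("morphodynamics", log_con, {
    pooled <- do.call(rbind, lapply(tables, function(t) {
      as.data.frame(t)[, c("polar_radius_norm", "incline")]
    }))
    dt <- dip_test(pooled$incline, n_boot = config$dip_n_boot, seed = config$seed)
    lw <- lowess_trend(pooled$polar_radius_norm, pooled$incline, config$lowess_frac)
    utils::write.csv(
      data.frame(dip = dt$dip, p_value = dt$p_value, n = dt$n),
      file.path(out_dir, "reports", "incline_dip.csv"),
      row.names = FALSE
    )
    utils::write.csv(lw, file.path(out_dir, "reports", "incline_lowess.csv"),
      row.names = FALSE
    )
  })

  if (isTRUE(config$poles$enabled)) {
    .stage("poles", log_con, {
      sec_cfg <- config$sections[[1]]
      spec <- sec_cfg$spec
      if (!inherits(spec, "section_spec")) spec <- do.call(section_spec, spec)
      ring <- generate_gus_ring(spec)
      rp <- ring_profile(ring,
        radius = spec$zone_radii[["cambium_outer"]] / spec$pixel_size,
        width = config$poles$width, blur_sigma = config$poles$blur_sigma
      )
      post <- bayesian_period(rp)
      utils::write.csv(
        data.frame(period_px = post$period_px, density = post$density),
        file.path(out_dir, "reports", "pole_period_posterior.csv"),
        row.names = FALSE
      )
      utils::write.csv(
        data.frame(
          map_period_px = post$map_period_px,
          spacing_um = arc_spacing_um(post$map_period_px, spec$pixel_size),
          concentration = post$concentration
        ),
        file.path(out_dir, "reports", "pole_period_summary.csv"),
        row.names = FALSE
      )
    })
  }

  .stage("checksums", log_con, {
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    files <- files[!grepl("run.log$", files)]
    sums <- tools::md5sum(files)
    writeLines(
      sprintf("md5 %s %s", sums, basename(names(sums))),
      log_con
    )
  })
  invisible(list(tables = tables, out_dir = out_dir))
}

# attach ground-truth classes to a segmented feature table by matching each
# cell centroid to the truth label under it
.label_from_truth <- function(table, truth) {
  lab <- truth$label_map$labels
  xi <- .clip(as.integer(round(table$centroid_x)), 1L, ncol(lab))
  yi <- .clip(as.integer(round(table$centroid_y)), 1L, nrow(lab))
  tid <- lab[cbind(yi, xi)]
  cls <- rep(NA_character_, nrow(table))
  hit <- tid > 0L
  cls[hit] <- unname(truth$cell_classes[as.character(tid[hit])])
  out <- table[!is.na(cls), , drop = FALSE]
  out$class <- cls[!is.na(cls)]
  out
}
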