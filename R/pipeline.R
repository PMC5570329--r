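# End-to-end orchestration: generate -> (render/segment) -> fit -> analyze.

#' Configuration of an end-to-end synthetic run
#'
#' @param seed Integer seed driving every random stage.
#' @param layout An [array_layout()].
#' @param donor A [donor_profile()].
#' @param noise A [noise_model()].
#' @param schedule Frame times (min).
#' @param stages Stages to execute, subset of
#'   `c("generate", "images", "fit", "analyze")`. `"images"` routes the data
#'   through rendered frames and the segmenter instead of using the generated
#'   tables directly.
#' @param pixel_size Render/segment pixel size (um).
#' @param gate A [gate_config()], or `NULL` to estimate thresholds from data.
#' @param policy A [secretor_policy()].
#' @param immediate_cutoff Immediate-secretor cutoff (min).
#' @param lod Frequency reporting floor (fraction).
#' @param out_dir Optional output directory for delimited result tables.
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1, layout = array_layout(),
                       donor = donor_profile(), noise = noise_model(),
                       schedule = trace_schedule(),
                       stages = c("generate", "fit", "analyze"),
                       pixel_size = 2, gate = gate_config(),
                       policy = secretor_policy(), immediate_cutoff = 180,
                       lod = 1e-4, out_dir = NULL) {
  bad <- setdiff(stages, c("generate", "images", "fit", "analyze"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(seed = as.integer(seed), layout = layout, donor = donor,
                 noise = noise, schedule = schedule, stages = stages,
                 pixel_size = pixel_size, gate = gate, policy = policy,
                 immediate_cutoff = immediate_cutoff, lod = lod,
                 out_dir = out_dir),
            class = "run_config")
}

#' Phenotype/secretion analysis report
#'
#' Joins the gated cell table, the well occupancies and the per-bead
#' secretion calls into the assay's headline statistics: the single-cell
#' secretor frequency (with detection floor), the CD16 enrichment of
#' immediate secretors against the parent population, the onset-time
#' distribution with its early/late split at the mean, CD16/CD56 early-vs-
#' late comparisons, and the multi-cell cooperation test. Wells holding more
#' than one bead count as positive if any bead is positive, and their onset
#' time is the earliest bead's.
#'
#' @param cells Cell table (`cell_id`, `well_id`, `cd16_mfi`, `cd56_mfi`).
#' @param wells Occupancy table (`well_id`, `n_cells`, `n_beads`).
#' @param calls Bead call table from [fit_secretion_table()].
#' @param gate A [gate_config()] or `NULL` to estimate from the data.
#' @param immediate_cutoff Immediate-secretor cutoff (min).
#' @param lod Frequency reporting floor.
#' @return An `analysis_report` list; see Details.
#' @export
analyze_experiment <- function(cells, wells, calls, gate = gate_config(),
                               immediate_cutoff = 180, lod = 1e-4) {
  cells <- gate_cells(cells, gate)
  freq <- enumerate_frequency(wells, calls, lod = lod)

  # per-well earliest onset among secretor beads
  sec_calls <- calls[calls$is_secretor %in% TRUE, ]
  well_onset <- if (nrow(sec_calls)) {
    stats::aggregate(t_secrete_min ~ well_id, data = sec_calls, FUN = min)
  } else data.frame(well_id = character(0), t_secrete_min = numeric(0))

  # single-cell wells: cell-level secretion status
  single_wells <- wells$well_id[wells$n_cells == 1 & wells$n_beads >= 1]
  sc <- cells[cells$well_id %in% single_wells, ]
  sc$t_secrete <- well_onset$t_secrete_min[match(sc$well_id,
                                                 well_onset$well_id)]
  sc$is_secretor <- !is.na(sc$t_secrete)
  sc$immediate <- sc$is_secretor & sc$t_secrete <= immediate_cutoff
  gated <- sc[sc$phenotype_label != "ungated", ]

  enr <- if (any(gated$immediate) && nrow(gated) > 0) {
    enrichment_test(cd16_positive(gated$phenotype_label[gated$immediate]),
                    cd16_positive(gated$phenotype_label))
  } else NULL

  tsec <- sc$t_secrete[sc$is_secretor]
  tsummary <- if (length(tsec) >= 3) distribution_summary(tsec) else NULL
  el <- if (length(tsec) >= 2) split_early_late(tsec) else NULL

  early_late_marker <- NULL
  if (!is.null(el) && length(el$early) >= 3 && length(el$late) >= 3) {
    grp <- ifelse(gated$t_secrete[gated$is_secretor] < el$mean,
                  "early", "late")
    gsec <- gated[gated$is_secretor, ]
    early_late_marker <- list(
      cd16 = compare_groups(gsec$cd16_mfi[grp == "early"],
                            gsec$cd16_mfi[grp == "late"]),
      cd56 = compare_groups(gsec$cd56_mfi[grp == "early"],
                            gsec$cd56_mfi[grp == "late"])
    )
  }

  coop <- tryCatch(cooperation_test(wells, calls), error = function(e) NULL)

  structure(
    list(frequency = freq, enrichment = enr, t_secrete_summary = tsummary,
         early_late = el, early_late_marker = early_late_marker,
         cooperation = coop, cells = cells, single_cell_table = sc,
         immediate_cutoff = immediate_cutoff),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== nanowell secretion analysis ==\n")
  if (!is.null(x$frequency) && identical(x$frequency$status, "ok")) {
    cat(sprintf("single-cell secretor frequency: %s (%d / %d wells)\n",
                x$frequency$display, x$frequency$n_positive,
                x$frequency$n_eligible))
  }
  if (!is.null(x$t_secrete_summary)) {
    s <- x$t_secrete_summary
    cat(sprintf("t_secrete: n = %d, mean %.1f min, sd %.1f, skewness %.2f\n",
                s$n, s$mean, s$sd, s$skewness))
  }
  if (!is.null(x$enrichment)) {
    cat(sprintf("CD16+ enrichment in immediate secretors (<= %d min): OR %.2f, p = %.3g\n",
                x$immediate_cutoff, x$enrichment$odds_ratio,
                x$enrichment$p_value))
  }
  if (!is.null(x$cooperation)) print(x$cooperation)
  invisible(x)
}

.segment_dataset <- function(ds, pixel_size) {
  layout <- ds$layout
  f1 <- render_frames(ds, frame = 1,
                      channels = c("cd16", "cd56", "beads", "ifng"),
                      pixel_size = pixel_size)
  cell_obj <- segment_frame(f1$cd56, layout, pixel_size, psf_sigma = 2,
                            measure_img = f1$cd16, kind = "cell")
  cells <- tibble::tibble(cell_id = cell_obj$object_id,
                          well_id = cell_obj$well_id,
                          cd16_mfi = cell_obj$mfi,
                          cd56_mfi = cell_obj$detect_mfi)
  frame_objects <- vector("list", length(ds$schedule))
  frame_objects[[1]] <- segment_frame(f1$beads, layout, pixel_size,
                                      psf_sigma = 1.2, measure_img = f1$ifng,
                                      kind = "bead")
  for (f in seq_along(ds$schedule)[-1]) {
    fr <- render_frames(ds, frame = f, channels = c("beads", "ifng"),
                        pixel_size = pixel_size)
    frame_objects[[f]] <- segment_frame(fr$beads, layout, pixel_size,
                                        psf_sigma = 1.2,
                                        measure_img = fr$ifng, kind = "bead")
  }
  traces <- extract_bead_traces(frame_objects, ds$schedule)
  bead_counts <- table(frame_objects[[1]]$well_id)
  cell_counts <- table(cell_obj$well_id)
  wells <- tibble::tibble(
    well_id = ds$occupancy$well_id,
    n_cells = as.integer(cell_counts[ds$occupancy$well_id]),
    n_beads = as.integer(bead_counts[ds$occupancy$well_id])
  )
  wells$n_cells[is.na(wells$n_cells)] <- 0L
  wells$n_beads[is.na(wells$n_beads)] <- 0L
  list(cells = cells, wells = wells, traces = traces)
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the enabled stages in order: generate the synthetic dataset;
#' optionally render each frame and segment it back into tables; fit and
#' call every bead trace; run the phenotype/secretion analysis. Intermediate
#' tables and the report are written to `config$out_dir` when set, each with
#' a header comment carrying the configuration hash and seed.
#'
#' @param config A [run_config()].
#' @return A list with elements `dataset`, `cells`, `wells`, `traces`,
#'   `calls`, `report` (those produced by the enabled stages), `config_hash`
#'   and `seed`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  out <- list(config_hash = hash, seed = config$seed)
  if (!"generate" %in% config$stages) {
    warning("no generate stage enabled; returning an empty report")
    return(out)
  }
  ds <- generate_dataset(config$layout, config$donor, config$noise,
                         seed = config$seed, schedule = config$schedule)
  out$dataset <- ds
  if ("images" %in% config$stages) {
    seg <- .segment_dataset(ds, config$pixel_size)
    out$cells <- seg$cells; out$wells <- seg$wells; out$traces <- seg$traces
  } else {
    out$cells <- ds$cells; out$wells <- ds$occupancy; out$traces <- ds$traces
  }
  if ("fit" %in% config$stages) {
    out$calls <- fit_secretion_table(out$traces, config$policy,
                                     config$immediate_cutoff)
  }
  if ("analyze" %in% config$stages && !is.null(out$calls)) {
    out$report <- analyze_experiment(out$cells, out$wells, out$calls,
                                     gate = config$gate,
                                     immediate_cutoff = config$immediate_cutoff,
                                     lod = config$lod)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- sprintf("# nanosecrete run config_hash=%s seed=%d", hash,
                   config$seed)
    for (nm in c("cells", "wells", "traces", "calls")) {
      if (!is.null(out[[nm]])) {
        write_result_table(out[[nm]], file.path(config$out_dir,
                                                paste0(nm, ".tsv")), hdr)
      }
    }
    if (!is.null(out$report)) {
      if (!is.null(out$report$cooperation)) {
        write_result_table(out$report$cooperation$table,
                           file.path(config$out_dir, "cooperation.tsv"), hdr)
      }
      summ <- utils::capture.output(print(out$report))
      writeLines(c(hdr, summ), file.path(config$out_dir, "summary.txt"))
    }
  }
  out
}
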