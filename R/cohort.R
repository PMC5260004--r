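# Synthetic cohort generation: replicate chips per experimental group, with
# chip-to-chip variability in PS and a full rendered-image path, standing in
# for the study's raw microscopy data.

#' Cohort specification
#'
#' Defines a replicate experiment: one or more groups (each a barrier
#' condition, a tracer and a number of chips), a shared perfusion protocol
#' and imaging model, the chip-to-chip variability, and a master seed.
#' Chip-level variability enters only through the PS product, drawn
#' lognormally with mean equal to the group's preset PS and coefficient of
#' variation `chip_variability_cv`; measurement noise alone reproduces the
#' within-trace scatter. Per-chip seeds are derived from the master seed by
#' counter-based splitting (`seed + 1000003 * chip_index`, mod 2^31 - 1), so
#' a cohort is fully reproducible from `seed`.
#'
#' @param groups Tibble with columns `label` (character), `condition`
#'   (list-column of [barrier_condition()]), `tracer` (list-column of
#'   [tracer()]) and `n_chips`. Build rows with [cohort_group()].
#' @param geometry A [chip_geometry()].
#' @param protocol A [perfusion_protocol()].
#' @param imaging An [imaging_model()].
#' @param chip_variability_cv CV of the lognormal per-chip PS draw
#'   (default 0.3, the scale implied by the assay's reported SEMs).
#' @param seed Master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, geometry = default_geometry(),
                        protocol = perfusion_protocol(),
                        imaging = imaging_model(),
                        chip_variability_cv = 0.3, seed = 1L) {
  stop_if(!is.data.frame(groups) ||
            !all(c("label", "condition", "tracer", "n_chips") %in%
                   names(groups)),
          "`groups` must have columns label, condition, tracer, n_chips")
  stop_if(nrow(groups) < 1, "at least one group is required")
  stop_if(any(groups$n_chips < 1), "each group needs n_chips >= 1")
  stop_if(anyDuplicated(groups$label) > 0, "group labels must be unique")
  check_non_negative(chip_variability_cv, "chip_variability_cv")
  stopifnot(inherits(geometry, "chip_geometry"),
            inherits(protocol, "perfusion_protocol"),
            inherits(imaging, "imaging_model"))
  structure(
    list(groups = groups, geometry = geometry, protocol = protocol,
         imaging = imaging, chip_variability_cv = chip_variability_cv,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param label Group label.
#' @param condition,tracer,n_chips One group's barrier condition, tracer and
#'   replicate count.
#' @export
cohort_group <- function(label, condition, tracer, n_chips) {
  tibble::tibble(label = label, condition = list(condition),
                 tracer = list(tracer), n_chips = as.integer(n_chips))
}

#' Default three-group cohort
#'
#' Free Texas Red under the unrestricted, BBB and BTB presets, 6 chips per
#' group.
#'
#' @param n_chips Chips per group.
#' @param seed Master seed.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n_chips = 6, seed = 1L) {
  trd <- tracer_preset("free_trd")
  groups <- dplyr::bind_rows(
    cohort_group("unrestricted", condition_preset("unrestricted", "free_trd"),
                 trd, n_chips),
    cohort_group("BBB", condition_preset("BBB", "free_trd"), trd, n_chips),
    cohort_group("BTB", condition_preset("BTB", "free_trd"), trd, n_chips))
  cohort_spec(groups, seed = seed)
}

chip_seed <- function(master, index) {
  as.integer((as.numeric(master) + 1000003 * index) %% (2^31 - 1))
}

# lognormal with mean `m` and coefficient of variation `cv`
rlnorm_mean_cv <- function(n, m, cv) {
  if (cv == 0 || m == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# per-chip plan: group labels, indices, seeds and true parameters
cohort_plan <- function(spec) {
  rows <- purrr::map_dfr(seq_len(nrow(spec$groups)), function(i) {
    gr <- spec$groups[i, ]
    tibble::tibble(group = gr$label, chip_in_group = seq_len(gr$n_chips),
                   condition = gr$condition, tracer = gr$tracer)
  })
  rows$chip_index <- seq_len(nrow(rows))
  rows$chip_id <- sprintf("%s_chip%02d", rows$group, rows$chip_in_group)
  rows$seed <- chip_seed(spec$seed, rows$chip_index)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  rows$true_ps <- purrr::map2_dbl(rows$condition, rows$seed, function(cnd, s) {
    set.seed(s)
    rlnorm_mean_cv(1, cnd$ps_product, spec$chip_variability_cv)
  })
  rows
}

simulate_chip <- function(spec, plan_row) {
  cnd <- plan_row$condition[[1]]
  cnd$ps_product <- plan_row$true_ps
  trc <- plan_row$tracer[[1]]
  # Frame t = 0 is when the tracer front reaches the imaging field: the
  # outer channel fills convectively (plug flow) in V_PF/Q, fast relative
  # to barrier exchange, so the lumen starts at the inlet concentration.
  simulate_transport(spec$geometry, cnd, trc, spec$protocol,
                     outer_conc0 = trc$inlet_concentration)
}

render_chip <- function(spec, plan_row, traces) {
  img <- spec$imaging
  img$seed <- chip_seed(plan_row$seed, 1)  # renderer gets its own stream
  render_timelapse(traces, img)
}

#' Simulate a cohort in memory
#'
#' Runs the full generative path per chip (transport simulation, rendering,
#' ROI extraction) without touching disk, and returns the extracted
#' intensity traces in long form, ready for [fit_cohort()].
#'
#' @param spec A [cohort_spec()].
#' @return A tibble: `chip_id`, `group`, `true_ps`, plus the
#'   `intensity_trace` columns.
#' @examples
#' \donttest{
#' traces <- simulate_cohort_traces(default_cohort_spec(n_chips = 3))
#' fit_cohort(traces, zone = "auto")
#' }
#' @export
simulate_cohort_traces <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  plan <- cohort_plan(spec)
  purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    row <- plan[i, ]
    stack <- render_chip(spec, row, simulate_chip(spec, row))
    tr <- extract_traces(stack)
    tibble::tibble(chip_id = row$chip_id, group = row$group,
                   true_ps = row$true_ps, tr)
  })
}

#' Generate a cohort dataset on disk
#'
#' Writes, per chip, a multi-page 16-bit TIFF stack (+ JSON timing sidecar),
#' a JSON ROI file, and a ground-truth concentration-trace CSV; plus a
#' manifest CSV listing relative file paths, group labels, per-chip seeds
#' and true parameters. Running the same spec twice produces byte-identical
#' manifests and ground-truth files.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return The manifest as a tibble (also written to `manifest.csv`),
#'   invisibly.
#' @export
generate_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  plan <- cohort_plan(spec)

  manifest <- purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    row <- plan[i, ]
    traces <- simulate_chip(spec, row)
    stack <- render_chip(spec, row, traces)
    stack_rel <- paste0(row$chip_id, ".tif")
    roi_rel <- paste0(row$chip_id, "_rois.json")
    truth_rel <- paste0(row$chip_id, "_truth.csv")
    write_stack(stack, file.path(dir, stack_rel))
    write_rois(stack$rois, file.path(dir, roi_rel))
    write.csv(as.data.frame(traces[, c("time_min", "outer_conc",
                                       "central_conc")]),
              file.path(dir, truth_rel), row.names = FALSE)
    cnd <- row$condition[[1]]
    tibble::tibble(chip_id = row$chip_id, group = row$group,
                   stack_path = stack_rel, roi_path = roi_rel,
                   truth_path = truth_rel, seed = row$seed,
                   true_ps = row$true_ps,
                   true_efflux = cnd$efflux_clearance,
                   true_inhibition = cnd$inhibition_fraction)
  })
  write.csv(as.data.frame(manifest), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(manifest)
}

#' Quantify a generated cohort
#'
#' Reads every stack and ROI file listed in a cohort manifest and extracts
#' the per-frame intensity traces.
#'
#' @param dir Cohort directory containing `manifest.csv` (as written by
#'   [generate_cohort()]).
#' @param background_subtract Passed to [extract_traces()].
#' @return A long tibble of traces with `chip_id` and `group` columns,
#'   ready for [fit_cohort()].
#' @export
quantify_cohort <- function(dir, background_subtract = FALSE) {
  manifest_path <- file.path(dir, "manifest.csv")
  stop_if(!file.exists(manifest_path),
          sprintf("no manifest.csv in '%s'", dir))
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    stack <- read_stack(file.path(dir, manifest$stack_path[i]))
    rois <- read_rois(file.path(dir, manifest$roi_path[i]))
    tr <- extract_traces(stack, rois,
                         background_subtract = background_subtract)
    tibble::tibble(chip_id = manifest$chip_id[i], group = manifest$group[i],
                   tr)
  })
}
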