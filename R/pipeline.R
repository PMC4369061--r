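#' Default run configuration
#'
#' Nested configuration for the end-to-end pipeline: segmentation tunables,
#' quenching protocol timing, plants per tray and the run seed. Every field
#' can be overridden via a flat `key=value` config file ([read_config()]) or
#' programmatically.
#'
#' @return list of class `"run_config"`.
#' @export
default_config <- function() {
  structure(list(
    segmentation = segmentation_params(),
    timing = protocol_timing(),
    n_plants_per_tray = 2,
    seed = 1,
    log_level = "info"
  ), class = "run_config")
}

#' Read a flat key=value configuration file
#'
#' Lines look like `segmentation.canny_low = 15` or
#' `timing.sp_offsets_s = 8,18,28,48,68`; section prefixes address nested
#' fields, comma-separated values become numeric vectors, and `#` starts a
#' comment. Unknown keys raise an error naming the key.
#'
#' @param path config file path.
#' @param base configuration to override (default [default_config()]).
#' @return a `"run_config"` list.
#' @export
read_config <- function(path, base = default_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- base
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    parsed <- if (anyNA(num)) {
      if (val %in% c("true", "TRUE")) TRUE
      else if (val %in% c("false", "FALSE")) FALSE
      else val
    } else num
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      if (!parts %in% names(cfg)) stop("unknown config key: ", key)
      cfg[[parts]] <- parsed
    } else if (length(parts) == 2) {
      if (!parts[1] %in% names(cfg) || !parts[2] %in% names(cfg[[parts[1]]]))
        stop("unknown config key: ", key)
      cfg[[parts[1]]][[parts[2]]] <- parsed
    } else stop("unknown config key: ", key)
  }
  cfg
}

# write a CSV carrying a provenance header comment (version + config hash)
write_table_csv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("shootpheno"))
  writeLines(sprintf("# shootpheno %s config=%s", ver, config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Generate a complete demo dataset on disk
#'
#' Writes the directory layout the pipeline subcommands consume: tray images
#' (two plants per tray, three views, several measuring days, plants growing
#' between days), a calibration table, region-mean quenching traces per
#' plant and day (with group-specific generative trends in FM, so the slow
#' group shows a declining maximal PSII yield), group assignments, and
#' synthetic final-day fresh weights correlated with plant size. Everything
#' is deterministic under the seed.
#'
#' @param dir output directory (created).
#' @param seed integer seed.
#' @param days measuring days.
#' @param n_trays_per_group trays (of two plants) per cultivar group.
#' @return invisibly, the manifest data.frame.
#' @export
simulate_dataset <- function(dir, seed = 1, days = c(1, 11, 21),
                             n_trays_per_group = 2) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "traces"), showWarnings = FALSE)
  groups <- c(cultivarA = log(3.5) / 20, cultivarB = log(2.5) / 20)
  manifest <- NULL; trace_manifest <- NULL; group_rows <- NULL; fw_rows <- NULL
  plant_counter <- 0
  for (g in names(groups)) {
    r <- groups[[g]]
    for (tr in seq_len(n_trays_per_group)) {
      tray_id <- sprintf("%s_tray%d", g, tr)
      ids <- sprintf("%s_p%02d", g, plant_counter + 1:2)
      plant_counter <- plant_counter + 2
      # per-plant size factor: plants of a cohort differ in vigour, and the
      # same factor drives both rendered size and fresh weight
      size <- with_seed(seed + 53 * plant_counter,
                        exp(stats::rnorm(2, 0, 0.15)))
      group_rows <- rbind(group_rows, data.frame(plant_id = ids, group = g))
      for (d in days) {
        scale <- exp(r * d / 2)            # area ~ length^2
        specs <- lapply(seq_along(ids), function(i)
          plant_spec(stem_length_px = round(32 * scale * size[i]),
                     n_branches = 4, tendril_width_px = 1,
                     noise_sd = 4, background = "soil_texture",
                     width = 96, height = 128,
                     seed = seed + 7 * plant_counter + 13 * d + i))
        views <- lapply(specs, make_plant_views)
        for (v in c("top", "front", "side")) {
          left <- views[[1]]$images[[v]]; right <- views[[2]]$images[[v]]
          composite <- array(0, dim = c(dim(left)[1],
                                        dim(left)[2] + dim(right)[2], 3))
          composite[, seq_len(dim(left)[2]), ] <- left
          composite[, dim(left)[2] + seq_len(dim(right)[2]), ] <- right
          rel <- file.path("images",
                           sprintf("%s_day%02d_%s.png", tray_id, d, v))
          png::writePNG(composite / 255, file.path(dir, rel))
          manifest <- rbind(manifest, data.frame(
            tray_id = tray_id, day = d, view = v, path = rel,
            plant_ids = paste(ids, collapse = ";"), group = g))
        }
        # quenching traces: the slow group loses FM (and gains quenching)
        # with cold exposure, the fast group barely changes
        for (i in seq_along(ids)) {
          drop <- if (g == "cultivarA") 0.05 else 0.25
          fm_d <- 1000 * (1 - drop * d / max(days))
          spec <- trace_spec(F0 = 200, FM = fm_d,
                             Ft = 0.4 * fm_d, FMp = 0.7 * fm_d,
                             noise_sd = 3,
                             seed = seed + 31 * plant_counter + d + i)
          rel <- file.path("traces", sprintf("%s_day%02d.csv", ids[i], d))
          utils::write.csv(make_trace(spec), file.path(dir, rel),
                           row.names = FALSE)
          trace_manifest <- rbind(trace_manifest, data.frame(
            plant_id = ids[i], day = d, path = rel, group = g))
        }
      }
      # final-day fresh weight proportional to plant size, with noise
      fin_scale <- exp(r * max(days))
      fw_rows <- rbind(fw_rows, data.frame(
        plant_id = ids,
        fw_g = with_seed(seed + 97 + plant_counter,
                         0.02 * fin_scale * size^2 *
                           exp(stats::rnorm(2, 0, 0.05)))))
    }
  }
  calib <- data.frame(view = c("top", "front", "side"),
                      px_count = c(400, 500, 500),
                      known_mm2 = c(100, 100, 100))
  utils::write.csv(calib, file.path(dir, "calibration.csv"), row.names = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(trace_manifest, file.path(dir, "trace_manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(group_rows, file.path(dir, "groups.csv"), row.names = FALSE)
  utils::write.csv(fw_rows, file.path(dir, "fw.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Segment every tray image of a dataset
#'
#' Runs [segment_view()] and [split_tray()] over a manifest, producing one
#' pixel-area row per plant, view and day. Unreadable images are reported
#' and skipped (the run continues); the failures are attached as the
#' `"failures"` attribute.
#'
#' @param manifest data.frame with `tray_id`, `day`, `view`, `path`,
#'   `plant_ids` (ids separated by `;`), optional `group`.
#' @param config a `"run_config"`.
#' @param base_dir directory that `path` entries are relative to.
#' @param output_dir if non-NULL, per-plant mask and overlay PNGs are
#'   written there.
#' @return data.frame with `plant_id`, `group`, `day`, `view`, `area_px`.
#' @export
run_segment <- function(manifest, config = default_config(), base_dir = ".",
                        output_dir = NULL) {
  if (!is.null(output_dir))
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    ids <- strsplit(m$plant_ids, ";", fixed = TRUE)[[1]]
    res <- tryCatch({
      img <- read_rgb_image(file.path(base_dir, m$path))
      mask <- segment_view(img, config$segmentation)
      plants <- suppressWarnings(split_tray(mask, length(ids)))
      if (!is.null(output_dir)) {
        for (j in seq_along(ids)) {
          write_mask_png(plants[[j]], file.path(
            output_dir, sprintf("%s_day%02d_%s_mask.png", ids[j], m$day, m$view)))
        }
        write_overlay_png(img, mask, file.path(
          output_dir, sprintf("%s_day%02d_%s_overlay.png", m$tray_id, m$day,
                              m$view)))
      }
      data.frame(plant_id = ids,
                 group = if ("group" %in% names(m)) m$group else NA,
                 day = m$day, view = m$view,
                 area_px = vapply(plants, sum, numeric(1)))
    }, error = function(e) {
      message(sprintf("skipping %s: %s", m$path, conditionMessage(e)))
      failures <<- c(failures, m$path)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  out
}

#' Quenching analysis of every trace in a dataset
#'
#' @param trace_manifest data.frame with `plant_id`, `day`, `path`,
#'   optional `group`.
#' @param timing a [protocol_timing()].
#' @param base_dir directory that `path` entries are relative to.
#' @return data.frame with one row per plant and day: the four levels, F0'
#'   and the six yields.
#' @export
run_fluor <- function(trace_manifest, timing = protocol_timing(),
                      base_dir = ".") {
  rows <- lapply(seq_len(nrow(trace_manifest)), function(i) {
    m <- trace_manifest[i, ]
    tr <- read_trace_csv(file.path(base_dir, m$path))
    lv <- extract_levels(tr, timing)
    qy <- quantum_yields(lv)
    data.frame(plant_id = m$plant_id,
               group = if ("group" %in% names(m)) m$group else NA,
               day = m$day,
               F0 = lv$F0, FM = lv$FM, Ft = lv$Ft, FMp = lv$FMp, F0p = qy$F0p,
               phi_Po = qy$phi_Po, phi_P = qy$phi_P, phi_PSII = qy$phi_PSII,
               q_P = qy$q_P, phi_fD = qy$phi_fD, phi_NPQ = qy$phi_NPQ)
  })
  do.call(rbind, rows)
}

#' Group report tables: per-day statistics, growth rates, correlations
#'
#' Emits the report tables of a two-group screening: per-day Mann-Whitney
#' comparisons of total green area and NGA, group RGR series, per-day
#' median/quartile summaries of the six PSII yields per group, and (when
#' fresh weights are supplied) the Spearman correlation of final-day green
#' area with fresh weight per group. With fewer than two groups the
#' comparison tables are skipped with a notice.
#'
#' @param growth per-plant growth table with a `group` column.
#' @param fluor optional [run_fluor()] output.
#' @param fw optional data.frame `plant_id`, `fw_g`.
#' @return named list of data.frames.
#' @export
run_report <- function(growth, fluor = NULL, fw = NULL) {
  stopifnot(all(c("plant_id", "group", "day", "a_total", "nga") %in%
                  names(growth)))
  out <- list()
  grps <- sort(unique(growth$group))
  if (length(grps) >= 2) {
    g1 <- grps[1]; g2 <- grps[2]
    per_day <- lapply(sort(unique(growth$day)), function(d) {
      gd <- growth[growth$day == d, ]
      a <- gd[gd$group == g1, ]; b <- gd[gd$group == g2, ]
      ta <- mann_whitney_u(a$a_total, b$a_total)
      tn <- mann_whitney_u(a$nga, b$nga)
      data.frame(day = d, n1 = ta$n1, n2 = ta$n2,
                 U_area = ta$statistic, p_area = ta$p_value,
                 U_nga = tn$statistic, p_nga = tn$p_value)
    })
    out$area_tests <- do.call(rbind, per_day)
  } else {
    message("single group: comparison tables skipped")
  }
  out$rgr <- do.call(rbind, lapply(grps, function(g) {
    s <- rgr_series(growth[growth$group == g, ])
    cbind(group = g, s)
  }))
  if (!is.null(fluor)) {
    params <- c("phi_Po", "phi_P", "phi_PSII", "q_P", "phi_fD", "phi_NPQ")
    rows <- list()
    for (g in sort(unique(fluor$group))) for (d in sort(unique(fluor$day)))
      for (p in params) {
        v <- fluor[fluor$group == g & fluor$day == d, p]
        if (length(v) == 0) next
        q <- median_quartiles(v)
        rows[[length(rows) + 1]] <- data.frame(
          group = g, day = d, parameter = p,
          q1 = q$q1, median = q$median, q3 = q$q3, n = q$n)
      }
    out$yields <- do.call(rbind, rows)
  }
  if (!is.null(fw)) {
    last_day <- max(growth$day)
    fin <- merge(growth[growth$day == last_day, ], fw, by = "plant_id")
    out$fw_correlation <- do.call(rbind, lapply(sort(unique(fin$group)),
      function(g) {
        fg <- fin[fin$group == g, ]
        if (nrow(fg) < 3) return(NULL)
        s <- spearman_cor(fg$a_total, fg$fw_g)
        data.frame(group = g, rho = s$statistic, p = s$p_value, n = s$n1)
      }))
  }
  out
}

#' Run the full demo pipeline end to end
#'
#' `simulate -> segment -> growth -> fluor -> report` on a generated
#' dataset, writing all report tables (with provenance headers) under
#' `dir/output`. Deterministic under the seed.
#'
#' @param dir working directory for the dataset and outputs.
#' @param seed integer seed.
#' @param config a `"run_config"`.
#' @return invisibly, a list with `areas`, `growth`, `fluor` and `report`.
#' @export
run_demo <- function(dir, seed = 1, config = default_config()) {
  config$seed <- seed
  simulate_dataset(dir, seed = seed)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  calib <- calibrate(utils::read.csv(file.path(dir, "calibration.csv")))
  areas <- run_segment(manifest, config, base_dir = dir)
  growth <- growth_table(areas, calib)
  growth <- merge(growth,
                  utils::read.csv(file.path(dir, "groups.csv")),
                  by = "plant_id")
  growth <- growth[order(growth$plant_id, growth$day), ]
  fluor <- run_fluor(utils::read.csv(file.path(dir, "trace_manifest.csv")),
                     config$timing, base_dir = dir)
  fw <- utils::read.csv(file.path(dir, "fw.csv"))
  report <- run_report(growth, fluor, fw)
  outdir <- file.path(dir, "output")
  dir.create(outdir, showWarnings = FALSE)
  write_table_csv(areas, file.path(outdir, "areas.csv"), config)
  write_table_csv(growth, file.path(outdir, "growth.csv"), config)
  write_table_csv(fluor, file.path(outdir, "fluor.csv"), config)
  for (nm in names(report))
    write_table_csv(report[[nm]], file.path(outdir, paste0(nm, ".csv")), config)
  invisible(list(areas = areas, growth = growth, fluor = fluor,
                 report = report))
}
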