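#' Read and write point clouds (ascii PLY, XYZ, CSV)
#'
#' Units are mm throughout. CSV carries the full cloud (header
#' `x,y,z[,nx,ny,nz][,label]`); ascii PLY carries coordinates and normals
#' (`element vertex` with `x,y,z[,nx,ny,nz]` properties); XYZ is bare
#' whitespace-delimited `x y z` lines. Coordinates round-trip to 1e-6 mm,
#' labels and normals exactly (CSV/PLY). Malformed rows error with their
#' line number.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"ply"`, `"xyz"` or `"csv"`.
#' @return `read_point_cloud()`: a `point_cloud`. `write_point_cloud()`:
#'   the path, invisibly.
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "xyz", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     ply = "ply", xyz = "xyz", csv = "csv",
                     abort(paste0("unknown point-cloud extension: ", path,
                                  " (pass `format` explicitly)")))
  }
  switch(format,
         ply = read_ply_ascii(path),
         xyz = read_xyz(path),
         csv = read_cloud_csv(path))
}

#' @rdname read_point_cloud
#' @param cloud A point cloud.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "ply", "xyz", "csv")) {
  format <- match.arg(format)
  cloud <- as_point_cloud(cloud)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     ply = "ply", xyz = "xyz", csv = "csv",
                     abort(paste0("unknown point-cloud extension: ", path)))
  }
  switch(format,
    ply = {
      nrm <- has_normals(cloud)
      props <- c("property double x", "property double y", "property double z",
                 if (nrm) c("property double nx", "property double ny",
                            "property double nz"))
      header <- c("ply", "format ascii 1.0",
                  paste("element vertex", nrow(cloud)), props, "end_header")
      cols <- c("x", "y", "z", if (nrm) c("nx", "ny", "nz"))
      body <- do.call(paste, lapply(cloud[cols], function(v) sprintf("%.9g", v)))
      writeLines(c(header, body), path)
    },
    xyz = {
      body <- sprintf("%.9g %.9g %.9g", cloud$x, cloud$y, cloud$z)
      writeLines(body, path)
    },
    csv = {
      cols <- intersect(c("x", "y", "z", "nx", "ny", "nz", "label"), names(cloud))
      readr::write_csv(as.data.frame(cloud)[cols], path)
    })
  invisible(path)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply") {
    abort(paste0(path, ": line 1: not an ascii PLY file (missing 'ply' magic)"))
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) abort(paste0(path, ": no end_header line"))
  header <- trimws(lines[2:(end - 1)])
  if (!any(grepl("^format\\s+ascii", header))) {
    abort(paste0(path, ": only ascii PLY is supported"))
  }
  props <- character(0)
  n_vertex <- NA_integer_
  in_vertex <- FALSE
  for (i in seq_along(header)) {
    tok <- strsplit(header[i], "\\s+")[[1]]
    if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) n_vertex <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex) {
      props <- c(props, tok[length(tok)])
    }
  }
  if (is.na(n_vertex)) abort(paste0(path, ": no 'element vertex' declaration"))
  need <- c("x", "y", "z")
  if (!all(need %in% props)) {
    abort(paste0(path, ": vertex element lacks x, y, z properties"))
  }
  body <- lines[(end + 1):(end + n_vertex)]
  if (length(body) < n_vertex || anyNA(body)) {
    abort(sprintf("%s: expected %d vertex rows after line %d", path, n_vertex, end))
  }
  vals <- strsplit(trimws(body), "\\s+")
  for (i in seq_along(vals)) {
    if (length(vals[[i]]) != length(props)) {
      abort(sprintf("%s: line %d: expected %d values, found %d",
                    path, end + i, length(props), length(vals[[i]])))
    }
  }
  M <- matrix(suppressWarnings(as.numeric(unlist(vals))),
              ncol = length(props), byrow = TRUE)
  bad <- which(rowSums(is.na(M)) > 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: non-numeric vertex value", path, end + bad[1]))
  }
  colnames(M) <- props
  out <- tibble::as_tibble(M[, intersect(c("x", "y", "z", "nx", "ny", "nz"),
                                         props), drop = FALSE])
  if (has_normals(out)) {  # re-unitise against ascii truncation
    len <- sqrt(out$nx^2 + out$ny^2 + out$nz^2)
    out$nx <- out$nx / len; out$ny <- out$ny / len; out$nz <- out$nz / len
  }
  as_point_cloud(out)
}

read_xyz <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines_keep <- which(nzchar(lines))
  vals <- strsplit(lines[lines_keep], "\\s+")
  for (i in seq_along(vals)) {
    if (length(vals[[i]]) != 3) {
      abort(sprintf("%s: line %d: expected 3 values per XYZ row", path,
                    lines_keep[i]))
    }
  }
  M <- matrix(suppressWarnings(as.numeric(unlist(vals))), ncol = 3, byrow = TRUE)
  bad <- which(rowSums(is.na(M)) > 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: non-numeric value", path, lines_keep[bad[1]]))
  }
  as_point_cloud(tibble::tibble(x = M[, 1], y = M[, 2], z = M[, 3]))
}

read_cloud_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("x", "y", "z"), names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: line 1: header lacks column(s) %s", path,
                  paste(missing, collapse = ", ")))
  }
  as_point_cloud(df)
}

#' Serialise a RANSAC fit to JSON
#'
#' Writes (or returns) the model parameters, ITPR, RMSE and configuration
#' echo of a fit as JSON.
#'
#' @param fit A `ransac_fit`.
#' @param path Optional output path; omit to return the JSON string.
#' @return The JSON string (invisibly when written to `path`).
#' @export
fit_to_json <- function(fit, path = NULL) {
  m <- fit$model
  model <- switch(m$kind,
    plane = list(kind = "plane", normal = m$normal, offset = m$offset),
    sphere = list(kind = "sphere", center = m$center, radius = m$radius),
    cylinder = list(kind = "cylinder", anchor = m$anchor, axis = m$axis,
                    radius = m$radius))
  obj <- list(model = model, itpr = fit$itpr, rmse = fit$rmse,
              rmse_all = fit$rmse_all, n_points = fit$n_points,
              n_inliers = fit$n_inliers,
              config = list(shape = fit$shape, epsilon = fit$epsilon,
                            iterations = fit$iterations_run, seed = fit$seed,
                            refined = fit$refined))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write study outputs to a directory
#'
#' Emits `records.csv` (specimen, level, region, group, side, shape,
#' epsilon, itpr, rmse, seed — the raw per-level ITPR table), the summary
#' CSVs, and `manifest.json` echoing the configuration and seeds so a run
#' can be reproduced bitwise.
#'
#' @param study A `congruence_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$records, file.path(dir, "records.csv"))
  readr::write_csv(study$group_summary, file.path(dir, "group_summary.csv"))
  readr::write_csv(study$region_summary, file.path(dir, "region_summary.csv"))
  readr::write_csv(study$table1, file.path(dir, "table1.csv"))
  readr::write_csv(study$reductions, file.path(dir, "reductions.csv"))
  manifest <- c(study$config,
                list(seeds = sort(unique(study$records$seed)),
                     n_records = nrow(study$records),
                     n_aborted = nrow(study$aborted)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a study configuration from YAML
#'
#' A study config has exactly one input mode — a synthetic `cohort` block
#' (`n_specimens`, `levels`, `jitter_sd`, `relief_scale`, `seed`) or an
#' `input_dir` with per-file clouds — plus the fitting settings (`epsilon`
#' or a `sensitivity` grid, `iterations`, `repeats`, `alpha`, `out`).
#'
#' @param path YAML file path.
#' @return A validated named list with defaults filled in.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path))
  cfg <- yaml::read_yaml(path)
  has_cohort <- !is.null(cfg$cohort)
  has_dir <- !is.null(cfg$input_dir)
  if (has_cohort == has_dir) {
    abort("config must have exactly one of `cohort` or `input_dir`")
  }
  defaults <- list(epsilon = 0.5, iterations = 100, repeats = 20,
                   alpha = 0.05, seed = 1, out = "study_out")
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  if (cfg$epsilon <= 0) abort("epsilon must be positive")
  if (cfg$iterations < 1) abort("iterations must be at least 1")
  cfg
}
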