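#' Read FreeSurfer-style morphometry tables
#'
#' Reads cortical-thickness and volume tables in the tab-separated layout
#' produced by FreeSurfer's `aparcstats2table` / `asegstats2table` commands:
#' one row per subject, first column the subject identifier, remaining
#' columns region or structure measures. Region names are normalized to
#' lowercase Desikan-Killiany labels with the hemisphere kept as a separate
#' field (`lh_precentral_thickness` -> hemi `lh`, region `precentral`);
#' structure names are lowercased with hyphens mapped to underscores
#' (`Right-Putamen` -> `right_putamen`). The whole-brain gray-matter volume
#' (`TotalGrayVol`) and topological surface-hole count (`SurfaceHoles`, the
#' proxy for damaged tissue volume) are mapped to dedicated fields.
#' Unrecognized columns are carried through untouched under a raw namespace.
#'
#' @param aparc_paths Named list or vector with elements `lh` and `rh`:
#'   paths to the left/right hemisphere thickness tables.
#' @param aseg_path Path to the volume table.
#' @return An object of class `morphometry_set`: a list of tibbles
#'   `thickness` (subject_id, hemi, region, thickness_mm), `volumes`
#'   (subject_id, structure, volume), `globals` (subject_id,
#'   total_gray_volume, surface_holes) and `raw` (unrecognized columns).
#' @export
read_morphometry <- function(aparc_paths, aseg_path) {
  stopifnot(all(c("lh", "rh") %in% names(aparc_paths)))
  th <- list()
  raw <- list()
  for (hemi in c("lh", "rh")) {
    tab <- read_stats_table(aparc_paths[[hemi]])
    cols <- names(tab)[-1]
    is_thick <- grepl(paste0("^", hemi, "_.+_thickness$"), cols)
    regions <- tolower(sub("_thickness$", "", sub(paste0("^", hemi, "_"), "", cols)))
    for (j in which(is_thick)) {
      th[[length(th) + 1L]] <- tibble::tibble(
        subject_id = tab[[1]], hemi = hemi, region = regions[j],
        thickness_mm = tab[[j + 1L]])
    }
    for (j in which(!is_thick)) {
      raw[[length(raw) + 1L]] <- tibble::tibble(
        subject_id = tab[[1]], table = basename(aparc_paths[[hemi]]),
        column = cols[j], value = tab[[j + 1L]])
    }
  }
  thickness <- do.call(rbind, th)
  bad <- thickness$thickness_mm <= 0 | thickness$thickness_mm >= 6
  if (any(bad)) {
    stop("thickness out of the plausible (0, 6) mm range for ",
         thickness$subject_id[which(bad)[1]], " ", thickness$hemi[which(bad)[1]],
         " ", thickness$region[which(bad)[1]])
  }

  aseg <- read_stats_table(aseg_path)
  aparc_subjects <- sort(unique(thickness$subject_id))
  aseg_subjects <- sort(aseg[[1]])
  if (!setequal(aparc_subjects, aseg_subjects)) {
    stop("subject sets differ between aparc and aseg tables: ",
         paste(symdiff_chr(aparc_subjects, aseg_subjects), collapse = ", "))
  }
  cols <- names(aseg)[-1]
  norm <- gsub("-", "_", tolower(cols))
  globals <- tibble::tibble(subject_id = aseg[[1]],
                            total_gray_volume = NA_real_,
                            surface_holes = NA_real_)
  vols <- list()
  for (j in seq_along(cols)) {
    if (norm[j] == "totalgrayvol") {
      globals$total_gray_volume <- aseg[[j + 1L]]
    } else if (norm[j] == "surfaceholes") {
      globals$surface_holes <- aseg[[j + 1L]]
    } else {
      vols[[length(vols) + 1L]] <- tibble::tibble(
        subject_id = aseg[[1]], structure = norm[j], volume = aseg[[j + 1L]])
    }
  }
  volumes <- if (length(vols) > 0) do.call(rbind, vols) else
    tibble::tibble(subject_id = character(0), structure = character(0),
                   volume = numeric(0))
  if (any(volumes$volume < 0) ||
      any(stats::na.omit(c(globals$total_gray_volume, globals$surface_holes)) < 0)) {
    stop("volumes and surface-hole counts must be non-negative")
  }
  raw <- if (length(raw) > 0) do.call(rbind, raw) else
    tibble::tibble(subject_id = character(0), table = character(0),
                   column = character(0), value = numeric(0))
  out <- structure(list(thickness = sort_by_cols(thickness, c("subject_id", "hemi", "region")),
                        volumes = sort_by_cols(volumes, c("subject_id", "structure")),
                        globals = sort_by_cols(globals, "subject_id"),
                        raw = raw),
                   class = "morphometry_set")
  out
}

read_stats_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0 || ncol(tab) < 2) {
    stop("not a subject-by-measure stats table (empty or single column): ", path)
  }
  for (j in 2:ncol(tab)) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    if (anyNA(v)) {
      row <- which(is.na(v))[1]
      stop("non-numeric cell in ", basename(path), " at row ", row,
           ", column '", names(tab)[j], "': '", tab[[j]][row], "'")
    }
    tab[[j]] <- v
  }
  tab[[1]] <- as.character(tab[[1]])
  tab
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))

sort_by_cols <- function(df, cols) {
  df[do.call(order, unname(as.list(df[cols]))), , drop = FALSE]
}

#' @export
print.morphometry_set <- function(x, ...) {
  cat(sprintf("<morphometry_set> %d subjects, %d thickness regions/hemi, %d structures\n",
              nrow(x$globals), length(unique(x$thickness$region)),
              length(unique(x$volumes$structure))))
  invisible(x)
}

#' Write a morphometry set back to FreeSurfer-style tables
#'
#' @param ms A `morphometry_set`.
#' @param dir Output directory; writes `lh.aparc.thickness.tsv`,
#'   `rh.aparc.thickness.tsv` and `aseg.volume.tsv`.
#' @return Named list of paths (`lh`, `rh`, `aseg`), invisibly.
#' @export
write_morphometry <- function(ms, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(lh = file.path(dir, "lh.aparc.thickness.tsv"),
                rh = file.path(dir, "rh.aparc.thickness.tsv"),
                aseg = file.path(dir, "aseg.volume.tsv"))
  subjects <- sort(unique(ms$globals$subject_id))
  for (hemi in c("lh", "rh")) {
    th <- ms$thickness[ms$thickness$hemi == hemi, , drop = FALSE]
    regions <- sort(unique(th$region))
    wide <- data.frame(subject = subjects, check.names = FALSE)
    names(wide)[1] <- paste0(hemi, ".aparc.thickness")
    for (r in regions) {
      v <- th$thickness_mm[match(paste(subjects, r),
                                 paste(th$subject_id, th$region))]
      wide[[paste0(hemi, "_", r, "_thickness")]] <- v
    }
    utils::write.table(wide, paths[[hemi]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wide <- data.frame(subject = subjects, check.names = FALSE)
  names(wide)[1] <- "Measure:volume"
  for (s in sort(unique(ms$volumes$structure))) {
    v <- ms$volumes$volume[match(paste(subjects, s),
                                 paste(ms$volumes$subject_id, ms$volumes$structure))]
    wide[[aseg_column_name(s)]] <- v
  }
  g <- ms$globals[match(subjects, ms$globals$subject_id), ]
  wide[["TotalGrayVol"]] <- g$total_gray_volume
  wide[["SurfaceHoles"]] <- g$surface_holes
  utils::write.table(wide, paths$aseg, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

aseg_column_name <- function(s) {
  # right_putamen -> Right-Putamen; keeps the FreeSurfer capitalization style
  parts <- strsplit(s, "_", fixed = TRUE)[[1]]
  paste(paste0(toupper(substring(parts, 1, 1)), substring(parts, 2)),
        collapse = "-")
}

#' Extract a scalar covariate per subject from morphometry + clinical data
#'
#' Resolves the covariate names used by the correlation battery:
#' `total_gray_volume`, `surface_holes`, any structure in the volume table
#' (e.g. `right_putamen`, `right_insula`), `gose`, `gcs`, or
#' `<region>_thickness` (mean of both hemispheres, e.g.
#' `precentral_thickness`).
#'
#' @param name Covariate name.
#' @param morphometry A `morphometry_set`.
#' @param clinical Data frame from [read_clinical()] (needed for `gose`/`gcs`).
#' @param subjects Character vector giving the subject order of the result.
#' @return Named numeric vector over `subjects`.
#' @export
subject_covariate <- function(name, morphometry, clinical = NULL, subjects) {
  g <- morphometry$globals
  value <- if (name %in% c("total_gray_volume", "surface_holes")) {
    g[[name]][match(subjects, g$subject_id)]
  } else if (name %in% c("gose", "gcs")) {
    if (is.null(clinical)) stop("clinical table required for covariate '", name, "'")
    clinical[[name]][match(subjects, clinical$subject_id)]
  } else if (name %in% morphometry$volumes$structure) {
    v <- morphometry$volumes[morphometry$volumes$structure == name, ]
    v$volume[match(subjects, v$subject_id)]
  } else if (grepl("_thickness$", name)) {
    region <- sub("_thickness$", "", name)
    th <- morphometry$thickness[morphometry$thickness$region == region, ]
    if (nrow(th) == 0) stop(unknown_covariate_msg(name, morphometry, clinical))
    tapply(th$thickness_mm, th$subject_id, mean)[subjects]
  } else {
    stop(unknown_covariate_msg(name, morphometry, clinical))
  }
  stats::setNames(as.numeric(value), subjects)
}

unknown_covariate_msg <- function(name, morphometry, clinical) {
  avail <- c("total_gray_volume", "surface_holes",
             unique(morphometry$volumes$structure),
             paste0(unique(morphometry$thickness$region), "_thickness"),
             if (!is.null(clinical)) c("gose", "gcs"))
  paste0("unknown covariate '", name, "'; available: ",
         paste(avail, collapse = ", "))
}

#' Read / write the per-subject clinical table
#'
#' Tab-separated with columns subject_id, group, gcs (Glasgow Coma Scale,
#' 3-15) and gose (Glasgow Outcome Scale-Extended, 1-8; higher is better).
#'
#' @param path File path.
#' @return Tibble with the validated columns.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "gcs", "gose")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop("clinical table missing column(s): ",
                             paste(miss, collapse = ", "))
  ok_gcs <- is.na(tab$gcs) | (tab$gcs >= 3 & tab$gcs <= 15)
  ok_gose <- is.na(tab$gose) | (tab$gose >= 1 & tab$gose <= 8)
  if (!all(ok_gcs)) stop("GCS out of [3, 15] for ", tab$subject_id[!ok_gcs][1])
  if (!all(ok_gose)) stop("GOSe out of [1, 8] for ", tab$subject_id[!ok_gose][1])
  tibble::as_tibble(tab[c("subject_id", "group", "gcs", "gose")])
}

#' @rdname read_clinical
#' @param clinical Data frame to write.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write result tables plus a machine-readable run manifest
#'
#' Each element of `tables` is coerced with [as.data.frame()] (cluster test
#' results flatten to one row per cluster) and written as a tab-separated
#' file `<name>.tsv` with deterministic column order; numeric values keep
#' full double precision. A `run_manifest.json` records the parameters,
#' seed and package/R versions.
#'
#' @param tables Named list of data frames or result objects.
#' @param out_dir Output directory (created if needed).
#' @param params Named list of run parameters recorded in the manifest.
#' @param seed Integer seed recorded in the manifest.
#' @return Tibble manifest (file, rows), invisibly.
#' @export
write_results <- function(tables, out_dir, params = list(), seed = NULL) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("'tables' must be a named list")
  }
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0); rows <- integer(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
    files <- c(files, basename(path)); rows <- c(rows, nrow(df))
  }
  manifest <- list(
    package = "tactileEEG",
    package_version = as.character(utils::packageVersion("tactileEEG")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    params = params,
    tables = as.list(stats::setNames(rows, files)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(tibble::tibble(file = files, rows = rows))
}
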