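## Dataset persistence: the 12-row CSV signal dialect (comma delimiter,
## '.' decimal, no header, %.6g), flat key=value parameter files, the
## case/split/run folder layout, anatomy-disjoint manifest construction
## and dialect validation.

.fmt <- function(v) sprintf("%.6g", v)

#' Dataset folder for a case label
#'
#' The LCX infarct folders split into anterior / posterior sub-folders by
#' the sampled center position (they remain one labeled sub-class).
#'
#' @param label One of [case_labels()].
#' @param sample Parameter row (used for the LCX split), optional.
#' @return Relative folder path.
#' @export
case_folder <- function(label, sample = NULL) {
  if (!grepl("^mi_", label)) return(label)
  parts <- strsplit(label, "_")[[1]]
  sub <- paste(parts[2], parts[3], sep = "_")
  if (parts[2] == "LCX" && !is.null(sample)) {
    side <- if (sample$mi_u < 0.5) "ant" else "post"
    sub <- paste(sub, side, sep = "_")
  }
  file.path("mi", sub)
}

#' Write one record in the dataset format
#'
#' Emits the record triple as three CSV files (12 rows of 5000
#' comma-separated mV values in the order I, II, III, aVR, aVL, aVF,
#' V1-V6) plus two flat `key=value` parameter files (atrial and
#' ventricular) carrying the full parameter sample for regeneration.
#'
#' @param record An `ecg_record`.
#' @param dir Output directory (created if needed).
#' @param run_id Run identifier, e.g. `"run_S62"`.
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_record <- function(record, dir, run_id) {
  stopifnot(inherits(record, "ecg_record"))
  for (v in c("raw", "noisy", "filtered")) {
    if (!all(dim(record[[v]]) == c(12, record$fs * 10))) {
      stop("record variant '", v, "' is not 12 x ", record$fs * 10)
    }
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    raw = file.path(dir, paste0(run_id, "_raw.csv")),
    noise = file.path(dir, paste0(run_id, "_noise.csv")),
    filtered = file.path(dir, paste0(run_id, "_filtered.csv")),
    atrial = file.path(dir, paste0(run_id, "_AtrialParameters.txt")),
    ventricular = file.path(dir, paste0(run_id, "_VentricularParameters.txt"))
  )
  for (pair in list(c("raw", "raw"), c("noisy", "noise"),
                    c("filtered", "filtered"))) {
    sig <- record[[pair[1]]]
    writeLines(apply(sig, 1, function(r) paste(.fmt(r), collapse = ",")),
               paths[pair[2]])
  }
  row <- record$meta$sample
  common <- c(run_id = run_id, label = record$label,
              seed = row$seed, snr_db = .fmt(record$snr_db),
              anatomy_id = record$meta$anatomy_id)
  akeys <- grep("^(cv_|pose_|torso_|fam_|lae_)", names(row), value = TRUE)
  vkeys <- setdiff(names(row), c(akeys, "seed"))
  kv <- function(keys) paste0(keys, "=", vapply(row[keys], .fmt, ""))
  writeLines(c(paste0(names(common), "=", common), kv(akeys)),
             paths["atrial"])
  writeLines(c(paste0(names(common), "=", common), kv(vkeys)),
             paths["ventricular"])
  invisible(paths)
}

#' Read a record written by [write_record()]
#'
#' @param prefix Path prefix (directory plus run id), or a named vector
#'   of the five paths.
#' @param strict Require exactly 5000 samples per row (the dataset
#'   length); otherwise any consistent length is accepted.
#' @return List with `raw`, `noisy`, `filtered` matrices, `params`
#'   (named list) and `fs` (500).
#' @export
read_record <- function(prefix, strict = TRUE) {
  paths <- if (length(prefix) == 1) {
    c(raw = paste0(prefix, "_raw.csv"), noise = paste0(prefix, "_noise.csv"),
      filtered = paste0(prefix, "_filtered.csv"),
      atrial = paste0(prefix, "_AtrialParameters.txt"),
      ventricular = paste0(prefix, "_VentricularParameters.txt"))
  } else prefix
  read_sig <- function(p) {
    ln <- sub("\r$", "", readLines(p))
    ln <- ln[nzchar(trimws(ln))]
    if (length(ln) != 12) {
      stop(basename(p), ": expected 12 rows, found ", length(ln))
    }
    vals <- lapply(strsplit(ln, ","), as.numeric)
    ns <- lengths(vals)
    if (length(unique(ns)) != 1) {
      stop(basename(p), ": inconsistent sample counts across rows")
    }
    if (strict && ns[1] != 5000) {
      stop(basename(p), ": expected 5000 samples per row, found ", ns[1])
    }
    out <- do.call(rbind, vals)
    rownames(out) <- LEAD_NAMES
    out
  }
  read_par <- function(p) {
    kv <- strsplit(readLines(p), "=", fixed = TRUE)
    stats::setNames(lapply(kv, function(x) {
      v <- paste(x[-1], collapse = "=")
      suppressWarnings(if (!is.na(as.numeric(v))) as.numeric(v) else v)
    }), vapply(kv, `[[`, "", 1))
  }
  list(raw = read_sig(paths["raw"]), noisy = read_sig(paths["noise"]),
       filtered = read_sig(paths["filtered"]),
       params = c(read_par(paths["atrial"]), read_par(paths["ventricular"])),
       fs = 500)
}

#' Build an anatomy-disjoint dataset manifest
#'
#' Assigns each anatomy to exactly one of the training / validation /
#' test splits (deterministically for a seed) and distributes
#' `n_per_case` runs per case round-robin over the anatomies, so every
#' anatomical model appears in a single split.
#'
#' @param n_per_case Runs per case.
#' @param anatomies Character or integer vector of anatomy identifiers
#'   (>= 3).
#' @param split_fractions Named fractions for `training`, `validation`,
#'   `test` (summing to 1).
#' @param seed Integer seed.
#' @param cases Case labels (defaults to all 13).
#' @return A `dataset_manifest`: data.frame with `case`, `run_id`,
#'   `anatomy_id`, `split`, `seed`.
#' @export
build_manifest <- function(n_per_case, anatomies,
                           split_fractions = c(training = 0.7,
                                               validation = 0.15,
                                               test = 0.15),
                           seed = 1, cases = case_labels()) {
  if (length(anatomies) < 3) stop("need at least 3 anatomies (one per split)")
  set.seed(as.integer(seed))
  sh <- sample(anatomies)
  n_a <- length(anatomies)
  cuts <- round(cumsum(split_fractions) * n_a)
  cuts <- pmax(cuts, seq_along(cuts))      # every split gets an anatomy
  split_of <- stats::setNames(rep(names(split_fractions)[3], n_a), sh)
  split_of[sh[seq_len(cuts[1])]] <- names(split_fractions)[1]
  if (cuts[2] > cuts[1]) {
    split_of[sh[(cuts[1] + 1):cuts[2]]] <- names(split_fractions)[2]
  }
  rows <- list()
  run_counter <- 0L
  for (cs in cases) {
    if (n_per_case == 0) next
    aid <- anatomies[((seq_len(n_per_case) - 1) %% n_a) + 1]
    rid <- paste0("run_S", run_counter + seq_len(n_per_case))
    run_counter <- run_counter + n_per_case
    rows[[cs]] <- data.frame(case = cs, run_id = rid, anatomy_id = aid,
                             split = unname(split_of[as.character(aid)]),
                             seed = seed + run_counter + seq_len(n_per_case))
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case = character(0), run_id = character(0),
               anatomy_id = character(0), split = character(0),
               seed = integer(0))
  rownames(df) <- NULL
  structure(df, cases = cases, class = c("dataset_manifest", "data.frame"))
}

#' Generate and persist a dataset tree
#'
#' Runs the full pipeline for every manifest row and writes the
#' case/split/run folder structure: signal CSVs under `signals/` and
#' parameter files under `parameters/`.
#'
#' @param out_dir Output root directory.
#' @param n_per_case Records per case.
#' @param seed Integer seed.
#' @param cases Case labels to generate.
#' @param n_anatomies Anatomy pool size.
#' @param resolution,atrial_resolution Mesh resolutions, mm.
#' @param config,params Configuration registries.
#' @param quiet Suppress progress messages.
#' @return The `dataset_manifest` with `path` column added, invisibly.
#' @export
generate_dataset <- function(out_dir, n_per_case = 2, seed = 1,
                             cases = case_labels(), n_anatomies = 3,
                             resolution = 2, atrial_resolution = 1.5,
                             config = default_synth_config(),
                             params = default_params(), quiet = FALSE) {
  mf <- build_manifest(n_per_case, seq_len(n_anatomies), seed = seed,
                       cases = cases)
  shapes <- lhs_sample(stats::setNames(
    rep(list(params$shape$atrial_coeff), 6), paste0("c", 1:6)
  ), max(n_anatomies, 2), seed + 7919)[seq_len(n_anatomies), , drop = FALSE]
  anatomies <- lapply(seq_len(n_anatomies), function(i) {
    build_anatomy_bundle(as.numeric(shapes[i, ]), params,
                         resolution, atrial_resolution)
  })
  mf$path <- NA_character_
  for (i in seq_len(nrow(mf))) {
    rows <- sample_case(1, mf$seed[i], params)
    cfg <- make_case_config(mf$case[i], rows[1, ], params)
    rec <- generate_record(cfg, anatomies[[mf$anatomy_id[i]]], config, params)
    rec$meta$anatomy_id <- mf$anatomy_id[i]
    folder <- case_folder(mf$case[i], rows[1, ])
    sig_dir <- file.path(out_dir, "signals", folder, mf$split[i])
    par_dir <- file.path(out_dir, "parameters", folder, mf$split[i])
    paths <- write_record(rec, sig_dir, mf$run_id[i])
    dir.create(par_dir, recursive = TRUE, showWarnings = FALSE)
    for (pf in c("atrial", "ventricular")) {
      file.rename(paths[pf], file.path(par_dir, basename(paths[pf])))
    }
    mf$path[i] <- file.path(sig_dir, mf$run_id[i])
    if (!quiet) message(mf$case[i], " ", mf$run_id[i], " written")
  }
  utils::write.csv(as.data.frame(mf), file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(mf)
}

#' Validate a dataset tree against the CSV dialect
#'
#' Checks every run: the three signal files exist, parse to 12 rows of
#' consistent (strictly 5000) finite samples, and the two parameter
#' files exist and parse.
#'
#' @param root Dataset root directory (from [generate_dataset()]).
#' @param strict Enforce the 5000-sample record length.
#' @return Data frame of violations (zero rows = valid).
#' @export
validate_dataset <- function(root, strict = TRUE) {
  sig_root <- file.path(root, "signals")
  raw_files <- list.files(sig_root, pattern = "_raw\\.csv$",
                          recursive = TRUE, full.names = TRUE)
  bad <- list()
  note <- function(f, msg) bad[[length(bad) + 1]] <<-
    data.frame(file = f, problem = msg)
  for (f in raw_files) {
    prefix <- sub("_raw\\.csv$", "", f)
    run <- basename(prefix)
    par_dir <- file.path(root, "parameters",
                         dirname(sub(paste0(sig_root, "/?"), "", f)))
    paths <- c(raw = f, noise = paste0(prefix, "_noise.csv"),
               filtered = paste0(prefix, "_filtered.csv"),
               atrial = file.path(par_dir,
                                  paste0(run, "_AtrialParameters.txt")),
               ventricular = file.path(par_dir,
                                       paste0(run,
                                              "_VentricularParameters.txt")))
    miss <- paths[!file.exists(paths)]
    if (length(miss)) {
      for (m in miss) note(m, "missing file")
      next
    }
    rec <- tryCatch(read_record(paths, strict = strict),
                    error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      note(f, rec)
    } else if (!all(vapply(rec[c("raw", "noisy", "filtered")],
                           function(m) all(is.finite(m)), logical(1)))) {
      note(f, "non-finite values")
    }
  }
  if (!length(bad)) {
    data.frame(file = character(0), problem = character(0))
  } else do.call(rbind, bad)
}
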