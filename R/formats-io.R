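#' Read a 3-column SAXS curve
#'
#' Parses the conventional whitespace-separated `q I sigma` dialect.
#' Comment lines start with `#`; rows with non-positive q or sigma, or
#' non-numeric fields, are dropped with a logged count.
#'
#' @param path Path to the text file.
#' @param label Profile label (default: file name).
#' @return A validated [saxs_profile()].
#' @export
read_saxs_dat <- function(path, label = basename(path)) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\\s+")
  vals <- suppressWarnings(
    lapply(fields, function(f) as.numeric(f[1:3]))
  )
  m <- do.call(rbind, vals)
  if (is.null(m)) abort(sprintf("'%s': no data rows.", path))
  ok <- stats::complete.cases(m) & m[, 1] > 0 & m[, 3] > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    lf_log("read_saxs_dat: dropped %d invalid row(s) from %s", n_dropped, path)
    warn(sprintf("read_saxs_dat: dropped %d invalid row(s).", n_dropped))
  }
  m <- m[ok, , drop = FALSE]
  if (nrow(m) < 8) {
    abort(sprintf("'%s': only %d valid rows (need >= 8).", path, nrow(m)))
  }
  out <- saxs_profile(m[, 1], m[, 2], m[, 3], label = label)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' @rdname read_saxs_dat
#' @param profile A `saxs_profile` to write.
#' @export
write_saxs_dat <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", attr(profile, "label") %||% ""), con)
  writeLines("# q I sigma", con)
  writeLines(sprintf("%.8g %.8g %.8g", profile$q, profile$i, profile$sigma),
             con)
  invisible(path)
}

#' Read / write a titration shift table
#'
#' The table is TSV with two comment header lines carrying the per-point
#' concentrations and paired shift columns per titration point:
#' ```
#' # P0\t100\t100\t...
#' # L0\t0\t20\t...
#' residue\tdomain\td_h_0\td_n_0\td_h_1\td_n_1\t...
#' ```
#' Residues missing (empty/NA) at one or more points are kept and flagged as
#' broadened from the first missing point onward, never silently dropped.
#'
#' @param path File path.
#' @return Tidy shift-table tibble: `residue`, `domain`, `point`, `p0`,
#'   `l0`, `d_h`, `d_n`, `broadened`.
#' @export
read_titration_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  p0_line <- hdr[grepl("^#\\s*P0", hdr)]
  l0_line <- hdr[grepl("^#\\s*L0", hdr)]
  if (length(p0_line) != 1 || length(l0_line) != 1) {
    abort("titration table must carry one '# P0' and one '# L0' header line.")
  }
  parse_conc <- function(x) as.numeric(strsplit(x, "\t")[[1]][-1])
  p0 <- parse_conc(p0_line)
  l0 <- parse_conc(l0_line)
  if (length(p0) != length(l0) || any(is.na(p0)) || any(is.na(l0))) {
    abort("malformed P0/L0 header lines.")
  }
  if (any(p0 < 0) || any(l0 < 0)) abort("concentrations must be >= 0.")
  if (!any(l0 == 0)) abort("no ligand-free (L0 = 0) reference point.")
  body <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                            check.names = FALSE)
  if (anyDuplicated(body$residue)) {
    abort(sprintf("duplicated residue id(s): %s",
                  paste(unique(body$residue[duplicated(body$residue)]),
                        collapse = ", ")))
  }
  npt <- length(p0)
  need <- as.vector(rbind(paste0("d_h_", 0:(npt - 1)),
                          paste0("d_n_", 0:(npt - 1))))
  if (!all(need %in% names(body))) abort("shift columns do not match P0/L0 headers.")
  ref_idx <- which(l0 == 0)[1] - 1L
  long <- body |>
    as_tibble() |>
    tidyr::pivot_longer(dplyr::all_of(need), names_to = c(".value", "point"),
                        names_pattern = "(d_[hn])_(\\d+)") |>
    dplyr::mutate(point = as.integer(.data$point),
                  p0 = p0[.data$point + 1L], l0 = l0[.data$point + 1L],
                  broadened = is.na(.data$d_h) | is.na(.data$d_n))
  missing_ref <- long |>
    dplyr::filter(.data$point == ref_idx, .data$broadened)
  if (nrow(missing_ref) > 0) {
    abort(sprintf("residue(s) %s missing at the L0 = 0 reference point.",
                  paste(missing_ref$residue, collapse = ", ")))
  }
  n_broad <- length(unique(long$residue[long$broadened]))
  if (n_broad > 0) lf_log("read_titration_table: %d broadened residue(s)", n_broad)
  cols <- c("residue", if ("domain" %in% names(long)) "domain",
            "point", "p0", "l0", "d_h", "d_n", "broadened")
  dplyr::arrange(long[cols], .data$residue, .data$point)
}

#' @rdname read_titration_table
#' @param shifts Shift-table tibble (from [simulate_titration()] or built by
#'   hand) with columns `residue`, `point`, `p0`, `l0`, `d_h`, `d_n` and
#'   optional `domain`.
#' @export
write_titration_table <- function(shifts, path) {
  pts <- shifts |>
    dplyr::distinct(.data$point, .data$p0, .data$l0) |>
    dplyr::arrange(.data$point)
  wide <- shifts |>
    dplyr::select(dplyr::any_of(c("residue", "domain")), "point", "d_h", "d_n") |>
    tidyr::pivot_wider(names_from = "point", values_from = c("d_h", "d_n"),
                       names_glue = "{.value}_{point}")
  shift_cols <- as.vector(rbind(paste0("d_h_", pts$point),
                                paste0("d_n_", pts$point)))
  wide <- wide[c(setdiff(names(wide), shift_cols), shift_cols)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("# P0", sprintf("%.8g", pts$p0)), collapse = "\t"), con)
  writeLines(paste(c("# L0", sprintf("%.8g", pts$l0)), collapse = "\t"), con)
  utils::write.table(wide, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single-chain Calpha trace as a bead model
#'
#' Accepts a PDB-format file with one Calpha (or single bead) per residue.
#' Multi-chain files and interior residues lacking a Calpha are rejected;
#' beads are ordered by residue number.
#'
#' @param path PDB file path.
#' @param domain,flexible Optional per-residue annotations (recycled rules as
#'   in [bead_model()]).
#' @return A validated [bead_model()].
#' @export
read_coordinates <- function(path, domain = NULL, flexible = NULL) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s'.", path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$elety %in% c("CA", "BB"), ]
  if (nrow(at) == 0) abort("no CA/bead records in file.")
  if (length(unique(at$chain[!is.na(at$chain)])) > 1) {
    abort("multi-chain file: the bead-model contract is single-chain.")
  }
  at <- at[order(at$resno), ]
  resno <- at$resno
  if (anyDuplicated(resno)) abort("duplicate CA records for a residue.")
  gaps <- which(diff(resno) != 1)
  if (length(gaps) > 0) {
    abort(sprintf("missing CA for interior residue %d (chain break).",
                  resno[gaps[1]] + 1L))
  }
  bead_model(cbind(at$x, at$y, at$z), residue = resno,
             domain = domain, flexible = flexible)
}

#' @rdname read_coordinates
#' @param model A `bead_model` to write (CA records, chain A).
#' @export
write_coordinates <- function(model, path) {
  xyz <- bead_coords(model)
  n <- nrow(xyz)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   resno = model$residue, chain = rep("A", n),
                   resid = rep("ALA", n), elety = rep("CA", n))
  invisible(path)
}

#' Read a structured configuration file
#'
#' YAML-style nested key/value configuration; values present in `defaults`
#' but absent from the file fall back to the default.
#'
#' @param path YAML file path.
#' @param defaults Named list of default values.
#' @return Named list.
#' @export
read_config <- function(path, defaults = list()) {
  cfg <- if (file.exists(path)) yaml::read_yaml(path) else
    abort(sprintf("cannot read '%s'.", path))
  utils::modifyList(defaults, cfg)
}

#' Write stage results and a run manifest
#'
#' Writes one plain-text TSV per result class plus `manifest.json` recording
#' the package version, configuration, seed and input digests. Reruns with
#' the same configuration and seed produce byte-identical outputs except for
#' the manifest timestamp.
#'
#' @param x A result object: `binding_fit`, `guinier_result`, `pofr`,
#'   `ensemble_models`, or any tibble.
#' @param dir Output directory (created if missing).
#' @param config Named list stored in the manifest.
#' @param seed Seed stored in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, dir, config = list(), seed = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'.", dir))
  }
  if (file.access(dir, 2) != 0) abort(sprintf("'%s' is not writable.", dir))
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- character(0)
  if (inherits(x, "binding_fit")) {
    paths <- c(tsv(x$residues, "kd_per_residue.tsv"),
               tsv(x$domains, "kd_table.tsv"))
  } else if (inherits(x, "guinier_result")) {
    paths <- tsv(glance(x), "guinier.tsv")
  } else if (inherits(x, "pofr")) {
    paths <- c(tsv(as_tibble(x), "pofr_curve.tsv"),
               tsv(glance(x), "pofr_summary.tsv"))
  } else if (inherits(x, "ensemble_models")) {
    if (nrow(x) == 0) {
      warn("write_results: empty ensemble list.")
      paths <- tsv(tibble(rank = integer(), n_states = integer(),
                          chi = numeric()), "ensembles.tsv")
    } else {
      paths <- tsv(tidy(x), "ensembles.tsv")
    }
  } else if (is.data.frame(x)) {
    paths <- tsv(x, "table.tsv")
  } else {
    abort("write_results: unsupported result class.")
  }
  manifest <- list(
    package = "linkerflex",
    version = as.character(packageVersion("linkerflex")),
    class = class(x)[1],
    config = config,
    seed = seed,
    files = basename(paths),
    digests = vapply(paths, function(p) {
      txt <- utf8ToInt(paste(readLines(p, warn = FALSE), collapse = "\n"))
      as.character(sum(txt * seq_along(txt)) %% 2^31)
    }, character(1), USE.NAMES = FALSE),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  lf_log("write_results: %d file(s) -> %s", length(paths) + 1, dir)
  invisible(c(paths, mpath))
}

#' Published dissociation constants for the STAM2 UIM-SH3 constructs
#'
#' The reported Kd table (uM, mean +/- SD) for the wild-type UIM-SH3 tandem
#' and its linker-deletion constructs binding mono-ubiquitin and Lys63-linked
#' diubiquitin, with the isotherm model used per entry. Ships with the
#' package as a plain TSV and serves as reference input for avidity-ratio
#' calculations and for ground-truth values in recovery studies.
#'
#' @return Tibble with columns `construct`, `domain`, `ligand`, `model`,
#'   `kd`, `kd_sd`.
#' @export
published_kd_table <- function() {
  path <- system.file("extdata", "published_kd_table.tsv",
                      package = "linkerflex", mustWork = TRUE)
  as_tibble(utils::read.delim(path))
}
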