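#' Table input/output and dialect handling
#'
#' The pipeline consumes three external table families: PrSM tables in a
#' TopPIC-style tab-separated dialect, proteoform tables in a
#' TDPortal/TDViewer-style export dialect, and MS1 intact-mass feature
#' tables in a ProMex-style dialect.  Engine versions rename columns, so
#' each reader takes a dialect object mapping internal fields to on-disk
#' column headers; the shipped defaults cover the common exports and every
#' entry can be overridden (e.g. from a YAML config).
#'
#' All readers normalize into one internal PrSM/feature representation
#' (a tibble), convert retention times to minutes at read time, and treat
#' the on-disk token "NA" as a true missing value (never 0).  Readers never
#' silently drop rows: rejected rows are reported with their index and
#' attached as an attribute, so `n_read + n_rejected = n_rows`.
#'
#' @name io_tables
NULL

#' Column dialect for TopPIC-style PrSM tables
#'
#' @param ... Named overrides for individual entries of the `columns` map,
#'   or for `rt_unit` / `cv_pattern`.
#' @return A list with elements `columns` (internal field -> header),
#'   `required` (internal fields that must be present), `rt_unit`
#'   (`"second"` or `"minute"`) and `cv_pattern`.
#' @export
toppic_dialect <- function(...) {
  d <- list(
    columns = c(
      file           = "Data file name",
      scan           = "Scan(s)",
      rt             = "Retention time",
      precursor_mass = "Precursor mass",
      adjusted_mass  = "Adjusted precursor mass",
      charge         = "Charge",
      evalue         = "E-value",
      qvalue         = "Proteoform-level Q-value",
      accession      = "Protein accession",
      gene           = "Gene",
      first_residue  = "First residue",
      last_residue   = "Last residue",
      proteoform     = "Proteoform",
      intensity      = "Feature intensity"
    ),
    required = c("scan", "rt", "precursor_mass", "charge", "evalue",
                 "accession", "first_residue", "last_residue", "proteoform"),
    rt_unit = "second",
    cv_pattern = "CV(-?[0-9]+)"
  )
  modify_dialect(d, ...)
}

#' Column dialect for TDPortal/TDViewer-style proteoform tables
#'
#' The exact TDViewer export schema varies between code sets; these
#' defaults are best-effort and every header is overridable.
#'
#' @inheritParams toppic_dialect
#' @return A dialect list, see [toppic_dialect()].
#' @export
tdportal_dialect <- function(...) {
  d <- list(
    columns = c(
      file          = "File Name",
      accession     = "Accession",
      gene          = "Gene",
      proteoform    = "Proteoform",
      mass          = "Monoisotopic Mass",
      rt            = "Retention Time",
      evalue        = "E-value",
      qvalue        = "Q-value",
      modifications = "Modifications",
      first_residue = "Start Index",
      last_residue  = "End Index"
    ),
    required = c("accession", "mass", "rt", "evalue"),
    rt_unit = "minute",
    cv_pattern = "CV(-?[0-9]+)"
  )
  modify_dialect(d, ...)
}

#' Column dialect for ProMex-style MS1 feature tables
#'
#' @inheritParams toppic_dialect
#' @return A dialect list, see [toppic_dialect()].
#' @export
promex_dialect <- function(...) {
  d <- list(
    columns = c(
      mono_mass  = "MonoMass",
      abundance  = "Abundance",
      rt_start   = "MinElutionTime",
      rt_end     = "MaxElutionTime",
      rt_apex    = "ApexElutionTime",
      charge_min = "MinCharge",
      charge_max = "MaxCharge"
    ),
    required = c("mono_mass", "abundance", "rt_start", "rt_end"),
    rt_unit = "minute",
    cv_pattern = "CV(-?[0-9]+)"
  )
  modify_dialect(d, ...)
}

modify_dialect <- function(d, ...) {
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm == "columns") {
      ov <- dots$columns
      d$columns[names(ov)] <- ov
    } else {
      d[[nm]] <- dots[[nm]]
    }
  }
  d
}

#' Split a raw-file name into run identifier and FAIMS compensation voltage
#'
#' FAIMS acquisitions are commonly split into one file per compensation
#' voltage (CV), with the voltage encoded in the file name
#' (e.g. `"..._CV40.raw"`).  The CV token is returned as the physical
#' (negative) voltage and the run id is the file stem with the token and
#' any extension removed.
#'
#' @param filename Character vector of file names or paths.
#' @param pattern Regular expression whose first capture group is the CV
#'   magnitude.
#' @param lenient If `TRUE`, names without a CV token get `cv = NA` instead
#'   of an error.
#' @return A tibble with columns `run_id` (character) and `cv` (integer,
#'   negative volts).
#' @examples
#' parse_run_cv("Hubmap_Intact_Brain_C1_CV40.raw")
#' @export
parse_run_cv <- function(filename, pattern = "CV(-?[0-9]+)", lenient = FALSE) {
  stem <- sub("\\.[A-Za-z0-9]+$", "", basename(filename))
  m <- stringr::str_match(stem, stringr::regex(pattern, ignore_case = TRUE))
  cv <- suppressWarnings(as.integer(m[, 2]))
  if (any(is.na(cv)) && !lenient) {
    bad <- stem[is.na(cv)]
    format_error(paste0("no CV token matching '", pattern, "' in: ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  cv <- -abs(cv)  # stored as the physical (negative) compensation voltage
  run_id <- stem
  ok <- !is.na(m[, 1])
  run_id[ok] <- mapply(function(s, tok) {
    s <- sub(paste0("[._-]?", tok, "[._-]?"), "", s, fixed = FALSE)
    sub("[._-]+$", "", s)
  }, stem[ok], vapply(m[ok, 1], function(x) {
    # escape the matched token for literal removal
    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
  }, character(1)))
  tibble::tibble(run_id = unname(run_id), cv = cv)
}

# Locate the header line of a TSV that may carry a free-text preamble
# (TopPIC writes its parameter block above the table).  Returns the number
# of lines to skip.
locate_header_skip <- function(path, probe_headers) {
  lines <- readr::read_lines(path, n_max = 200L)
  for (i in seq_along(lines)) {
    cells <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (all(probe_headers %in% cells)) return(i - 1L)
  }
  0L
}

#' Parse the modification annotations of a proteoform string
#'
#' Proteoform strings carry modifications in square brackets, optionally
#' scoped to residues by a preceding parenthesis group, e.g.
#' `"M.SGR(K)[Acetyl]GK[+446.956]GG.A"`.  A bracket item that is a bare
#' number is an unknown mass shift (open-modification search hit); a named
#' item is a known PTM, considered localized when its scope is a single
#' residue.  Multiple items may be joined with `&` or `;`.
#'
#' @param proteoform Character vector of proteoform strings.
#' @return A list of tibbles, one per input, with columns `name` (NA for
#'   bare shifts), `mass_shift` (Da, NA for named PTMs), `scope` and
#'   `localized`.
#' @export
parse_proteoform_mods <- function(proteoform) {
  lapply(proteoform, function(p) {
    if (is.na(p) || !nzchar(p)) {
      return(tibble::tibble(name = character(), mass_shift = double(),
                            scope = character(), localized = logical()))
    }
    m <- stringr::str_match_all(p, "(?:\\(([A-Za-z ]+)\\))?\\[([^\\]]+)\\]")[[1]]
    if (nrow(m) == 0) {
      return(tibble::tibble(name = character(), mass_shift = double(),
                            scope = character(), localized = logical()))
    }
    out <- lapply(seq_len(nrow(m)), function(i) {
      scope <- m[i, 2]
      items <- strsplit(m[i, 3], "[&;]")[[1]]
      items <- trimws(items)
      shift <- suppressWarnings(as.numeric(items))
      tibble::tibble(
        name = ifelse(is.na(shift), items, NA_character_),
        mass_shift = shift,
        scope = scope,
        localized = !is.na(scope) & nchar(gsub(" ", "", scope)) == 1L
      )
    })
    dplyr::bind_rows(out)
  })
}

has_unknown_mass_shift <- function(mods_list) {
  vapply(mods_list, function(m) any(is.na(m$name)), logical(1))
}

# Pull a column by internal field name through a dialect; returns NULL when
# the table does not carry it.
dialect_col <- function(df, dialect, field) {
  header <- dialect$columns[[field]]
  if (is.null(header) || !header %in% names(df)) return(NULL)
  df[[header]]
}

check_required <- function(df, dialect, path) {
  for (field in dialect$required) {
    header <- dialect$columns[[field]]
    if (!header %in% names(df)) {
      format_error(paste0("missing mandatory column '", header, "' (field '",
                          field, "') in ", path))
    }
  }
}

as_num <- function(x) suppressWarnings(as.numeric(x))
as_int <- function(x) suppressWarnings(as.integer(x))

finalize_prsms <- function(out, rejected_idx, reasons, path) {
  if (length(rejected_idx)) {
    message("read ", path, ": rejected ", length(rejected_idx), " row(s): ",
            paste0("#", rejected_idx, " (", reasons, ")", collapse = ", "))
    out <- out[-rejected_idx, , drop = FALSE]
  }
  attr(out, "rejected") <- tibble::tibble(row = rejected_idx, reason = reasons)
  out
}

#' Read a TopPIC-style PrSM table
#'
#' @param path Path to a tab-separated PrSM table (a TopPIC parameter
#'   preamble above the header is skipped automatically).
#' @param dialect Column dialect, see [toppic_dialect()].
#' @param run_id,cv Run identifier and FAIMS CV; when `NULL` they are
#'   derived per row from the data-file-name column (or from `path`).
#' @return A tibble of PrSM records with columns `engine`, `run_id`, `cv`,
#'   `scan`, `rt_min`, `precursor_mass`, `adjusted_mass`, `charge`,
#'   `evalue`, `qvalue`, `accession`, `gene`, `first_residue`,
#'   `last_residue`, `proteoform`, `intensity`, `modifications`
#'   (list-column) and `has_unknown_shift`.  Rows with unparseable masses
#'   are rejected and reported; the attribute `"rejected"` lists their
#'   indices and reasons.
#' @export
read_toppic_prsms <- function(path, dialect = toppic_dialect(),
                              run_id = NULL, cv = NULL) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  probe <- unname(dialect$columns[dialect$required[1:2]])
  skip <- locate_header_skip(path, probe)
  df <- readr::read_tsv(path, skip = skip, na = c("NA", ""), col_types = readr::cols(.default = "c"),
                        show_col_types = FALSE, progress = FALSE)
  check_required(df, dialect, path)
  n <- nrow(df)

  file_col <- dialect_col(df, dialect, "file")
  if (is.null(run_id)) {
    src <- if (!is.null(file_col)) file_col else rep(basename(path), n)
    rc <- parse_run_cv(src, dialect$cv_pattern, lenient = TRUE)
    run_id_v <- rc$run_id
    cv_v <- rc$cv
  } else {
    run_id_v <- rep(run_id, n)
    cv_v <- rep(if (is.null(cv)) NA_integer_ else as.integer(cv), n)
  }
  if (!is.null(cv)) cv_v <- rep(as.integer(cv), n)

  rt <- as_num(dialect_col(df, dialect, "rt"))
  if (identical(dialect$rt_unit, "second")) rt <- rt / 60

  pmass <- as_num(dialect_col(df, dialect, "precursor_mass"))
  amass_raw <- dialect_col(df, dialect, "adjusted_mass")
  amass <- if (is.null(amass_raw)) rep(NA_real_, n) else as_num(amass_raw)
  qv_raw <- dialect_col(df, dialect, "qvalue")
  gene_raw <- dialect_col(df, dialect, "gene")
  int_raw <- dialect_col(df, dialect, "intensity")

  pf <- as.character(dialect_col(df, dialect, "proteoform"))
  mods <- parse_proteoform_mods(pf)

  out <- tibble::tibble(
    engine = "toppic",
    run_id = run_id_v,
    cv = cv_v,
    scan = as.character(dialect_col(df, dialect, "scan")),
    rt_min = rt,
    precursor_mass = pmass,
    adjusted_mass = amass,
    charge = as_int(dialect_col(df, dialect, "charge")),
    evalue = as_num(dialect_col(df, dialect, "evalue")),
    qvalue = if (is.null(qv_raw)) NA_real_ else as_num(qv_raw),
    accession = as.character(dialect_col(df, dialect, "accession")),
    gene = if (is.null(gene_raw)) NA_character_ else as.character(gene_raw),
    first_residue = as_int(dialect_col(df, dialect, "first_residue")),
    last_residue = as_int(dialect_col(df, dialect, "last_residue")),
    proteoform = pf,
    intensity = if (is.null(int_raw)) NA_real_ else as_num(int_raw),
    modifications = mods,
    has_unknown_shift = has_unknown_mass_shift(mods)
  )
  raw_mass <- as.character(df[[dialect$columns[["precursor_mass"]]]])
  bad <- which(is.na(out$precursor_mass) | out$precursor_mass <= 0)
  reasons <- ifelse(is.na(raw_mass[bad]) | is.na(as_num(raw_mass[bad])),
                    "non-numeric precursor mass", "non-positive precursor mass")
  finalize_prsms(out, bad, reasons, path)
}

#' Read a TDPortal/TDViewer-style proteoform table
#'
#' Produces records in the same internal PrSM representation as
#' [read_toppic_prsms()], with `engine = "tdportal"` and the engine's
#' monoisotopic mass stored as `precursor_mass`.  A `Modifications` column
#' (semicolon-separated, `Name@position` for localized PTMs) is parsed when
#' present; bracketed annotations in the proteoform string are parsed as in
#' the TopPIC dialect.
#'
#' @inheritParams read_toppic_prsms
#' @param dialect Column dialect, see [tdportal_dialect()].
#' @return A tibble of PrSM records (see [read_toppic_prsms()]).
#' @export
read_tdportal_table <- function(path, dialect = tdportal_dialect(),
                                run_id = NULL, cv = NULL) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  probe <- unname(dialect$columns[dialect$required[1:2]])
  skip <- locate_header_skip(path, probe)
  df <- readr::read_tsv(path, skip = skip, na = c("NA", ""), col_types = readr::cols(.default = "c"),
                        show_col_types = FALSE, progress = FALSE)
  check_required(df, dialect, path)
  n <- nrow(df)

  file_col <- dialect_col(df, dialect, "file")
  if (is.null(run_id)) {
    src <- if (!is.null(file_col)) file_col else rep(basename(path), n)
    rc <- parse_run_cv(src, dialect$cv_pattern, lenient = TRUE)
    run_id_v <- rc$run_id
    cv_v <- rc$cv
  } else {
    run_id_v <- rep(run_id, n)
    cv_v <- rep(if (is.null(cv)) NA_integer_ else as.integer(cv), n)
  }

  rt <- as_num(dialect_col(df, dialect, "rt"))
  if (identical(dialect$rt_unit, "second")) rt <- rt / 60

  pf_raw <- dialect_col(df, dialect, "proteoform")
  pf <- if (is.null(pf_raw)) rep(NA_character_, n) else as.character(pf_raw)
  mods <- parse_proteoform_mods(pf)
  mod_col <- dialect_col(df, dialect, "modifications")
  if (!is.null(mod_col)) {
    extra <- parse_named_modifications(as.character(mod_col))
    mods <- mapply(function(a, b) dplyr::bind_rows(a, b), mods, extra,
                   SIMPLIFY = FALSE)
  }

  qv_raw <- dialect_col(df, dialect, "qvalue")
  gene_raw <- dialect_col(df, dialect, "gene")
  fr_raw <- dialect_col(df, dialect, "first_residue")
  lr_raw <- dialect_col(df, dialect, "last_residue")

  out <- tibble::tibble(
    engine = "tdportal",
    run_id = run_id_v,
    cv = cv_v,
    scan = NA_character_,
    rt_min = rt,
    precursor_mass = as_num(dialect_col(df, dialect, "mass")),
    adjusted_mass = NA_real_,
    charge = NA_integer_,
    evalue = as_num(dialect_col(df, dialect, "evalue")),
    qvalue = if (is.null(qv_raw)) NA_real_ else as_num(qv_raw),
    accession = as.character(dialect_col(df, dialect, "accession")),
    gene = if (is.null(gene_raw)) NA_character_ else as.character(gene_raw),
    first_residue = if (is.null(fr_raw)) NA_integer_ else as_int(fr_raw),
    last_residue = if (is.null(lr_raw)) NA_integer_ else as_int(lr_raw),
    proteoform = pf,
    intensity = NA_real_,
    modifications = mods,
    has_unknown_shift = has_unknown_mass_shift(mods)
  )
  raw_mass <- as.character(df[[dialect$columns[["mass"]]]])
  bad <- which(is.na(out$precursor_mass) | out$precursor_mass <= 0)
  reasons <- ifelse(is.na(raw_mass[bad]) | is.na(as_num(raw_mass[bad])),
                    "non-numeric mass", "non-positive mass")
  finalize_prsms(out, bad, reasons, path)
}

# "Acetyl@2; Phospho" -> named PTMs; "@pos" marks a localized site.
parse_named_modifications <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(tibble::tibble(name = character(), mass_shift = double(),
                            scope = character(), localized = logical()))
    }
    items <- trimws(strsplit(s, ";")[[1]])
    items <- items[nzchar(items)]
    loc <- grepl("@", items, fixed = TRUE)
    name <- sub("@.*$", "", items)
    shift <- suppressWarnings(as.numeric(name))
    tibble::tibble(
      name = ifelse(is.na(shift), name, NA_character_),
      mass_shift = shift,
      scope = ifelse(loc, sub("^.*@", "", items), NA_character_),
      localized = loc
    )
  })
}

#' Read a ProMex-style MS1 feature table
#'
#' @inheritParams read_toppic_prsms
#' @param dialect Column dialect, see [promex_dialect()].
#' @return A tibble of MS1 features with columns `run_id`, `cv`,
#'   `mono_mass`, `rt_apex`, `rt_start`, `rt_end`, `abundance`,
#'   `charge_min`, `charge_max`.  An on-disk "NA" abundance becomes a
#'   missing value; rows with negative abundance or unparseable mass are
#'   rejected and reported.  When the dialect's apex column is absent the
#'   apex defaults to the elution midpoint.
#' @export
read_promex_features <- function(path, dialect = promex_dialect(),
                                 run_id = NULL, cv = NULL) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  df <- readr::read_tsv(path, na = c("NA", ""), col_types = readr::cols(.default = "c"),
                        show_col_types = FALSE, progress = FALSE)
  check_required(df, dialect, path)
  n <- nrow(df)

  if (is.null(run_id)) {
    rc <- parse_run_cv(basename(path), dialect$cv_pattern, lenient = TRUE)
    run_id_v <- rep(rc$run_id, n)
    cv_v <- rep(rc$cv, n)
  } else {
    run_id_v <- rep(run_id, n)
    cv_v <- rep(if (is.null(cv)) NA_integer_ else as.integer(cv), n)
  }

  scale_rt <- if (identical(dialect$rt_unit, "second")) 1 / 60 else 1
  rt_start <- as_num(dialect_col(df, dialect, "rt_start")) * scale_rt
  rt_end <- as_num(dialect_col(df, dialect, "rt_end")) * scale_rt
  apex_raw <- dialect_col(df, dialect, "rt_apex")
  rt_apex <- if (is.null(apex_raw)) (rt_start + rt_end) / 2 else as_num(apex_raw) * scale_rt
  rt_apex <- ifelse(is.na(rt_apex), (rt_start + rt_end) / 2, rt_apex)
  cmin_raw <- dialect_col(df, dialect, "charge_min")
  cmax_raw <- dialect_col(df, dialect, "charge_max")

  out <- tibble::tibble(
    run_id = run_id_v,
    cv = cv_v,
    mono_mass = as_num(dialect_col(df, dialect, "mono_mass")),
    rt_apex = rt_apex,
    rt_start = rt_start,
    rt_end = rt_end,
    abundance = as_num(dialect_col(df, dialect, "abundance")),
    charge_min = if (is.null(cmin_raw)) NA_integer_ else as_int(cmin_raw),
    charge_max = if (is.null(cmax_raw)) NA_integer_ else as_int(cmax_raw)
  )
  bad_mass <- is.na(out$mono_mass) | out$mono_mass <= 0
  bad_ab <- !is.na(out$abundance) & out$abundance < 0
  bad <- which(bad_mass | bad_ab)
  reasons <- ifelse(bad_mass[bad], "unparseable mass", "negative abundance")
  if (length(bad)) {
    message("read ", path, ": rejected ", length(bad), " row(s): ",
            paste0("#", bad, " (", reasons, ")", collapse = ", "))
    out <- out[-bad, , drop = FALSE]
  }
  attr(out, "rejected") <- tibble::tibble(row = bad, reason = reasons)
  out
}

#' Read and write MALDI peak lists
#'
#' Peak lists are two-column text files (m/z, intensity), whitespace- or
#' tab-separated.  Peaks are sorted by m/z on read; exact duplicate m/z
#' values are merged by summing intensity so the m/z axis is strictly
#' increasing.
#'
#' @param path File path.
#' @return For the reader, a tibble with columns `mz` and `intensity`.
#' @export
read_maldi_peaks <- function(path) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  df <- utils::read.table(path, header = FALSE, col.names = c("mz", "intensity"),
                          colClasses = "numeric")
  out <- tibble::as_tibble(df)
  out <- dplyr::summarise(dplyr::group_by(out, .data$mz),
                          intensity = sum(.data$intensity), .groups = "drop")
  dplyr::arrange(out, .data$mz)
}

#' @rdname read_maldi_peaks
#' @param peaks A tibble with columns `mz` and `intensity`.
#' @export
write_maldi_peaks <- function(peaks, path) {
  readr::write_tsv(peaks[, c("mz", "intensity")], path, col_names = FALSE)
  invisible(path)
}

#' Write and re-read the final quantitation table
#'
#' Tab-separated, one row per feature group, annotation columns followed by
#' per-sample abundances and any statistics columns.  Missing values are
#' written as "NA".  The pair is a lossless round trip (up to double
#' formatting precision).
#'
#' @param tbl A tibble (typically from [as_quant_table()] or
#'   [run_pipeline()] output).
#' @param path Output path.
#' @export
write_quant_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, na = "NA")
  invisible(path)
}

#' @rdname write_quant_table
#' @export
read_quant_table <- function(path) {
  readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
}

#' Write internal records back to the on-disk engine dialects
#'
#' Counterparts of the readers, used by the synthetic-data generator and
#' for audit dumps.  Retention times are converted back to the dialect's
#' unit; missing values are written as "NA".
#'
#' @param prsms Internal PrSM tibble (see [read_toppic_prsms()]).
#' @param path Output path.
#' @param dialect Column dialect of the target format.
#' @name write_engine_tables
NULL

#' @rdname write_engine_tables
#' @export
write_toppic_table <- function(prsms, path, dialect = toppic_dialect()) {
  rt <- prsms$rt_min
  if (identical(dialect$rt_unit, "second")) rt <- rt * 60
  cv_tok <- ifelse(is.na(prsms$cv), "", paste0("_CV", abs(prsms$cv)))
  df <- tibble::tibble(
    a = paste0(prsms$run_id, cv_tok, ".raw"),
    b = prsms$scan, c = rt, d = prsms$precursor_mass, e = prsms$adjusted_mass,
    f = prsms$charge, g = prsms$evalue, h = prsms$qvalue, i = prsms$accession,
    j = prsms$gene, k = prsms$first_residue, l = prsms$last_residue,
    m = prsms$proteoform, n = prsms$intensity
  )
  names(df) <- unname(dialect$columns[c("file", "scan", "rt", "precursor_mass",
                                        "adjusted_mass", "charge", "evalue",
                                        "qvalue", "accession", "gene",
                                        "first_residue", "last_residue",
                                        "proteoform", "intensity")])
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' @rdname write_engine_tables
#' @export
write_tdportal_table <- function(prsms, path, dialect = tdportal_dialect()) {
  rt <- prsms$rt_min
  if (identical(dialect$rt_unit, "second")) rt <- rt * 60
  cv_tok <- ifelse(is.na(prsms$cv), "", paste0("_CV", abs(prsms$cv)))
  df <- tibble::tibble(
    a = paste0(prsms$run_id, cv_tok, ".raw"),
    b = prsms$accession, c = prsms$gene, d = prsms$proteoform,
    e = prsms$precursor_mass, f = rt, g = prsms$evalue, h = prsms$qvalue,
    i = prsms$first_residue, j = prsms$last_residue
  )
  names(df) <- unname(dialect$columns[c("file", "accession", "gene",
                                        "proteoform", "mass", "rt", "evalue",
                                        "qvalue", "first_residue",
                                        "last_residue")])
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' @rdname write_engine_tables
#' @param features Internal MS1 feature tibble (see
#'   [read_promex_features()]).
#' @export
write_promex_table <- function(features, path, dialect = promex_dialect()) {
  scale_rt <- if (identical(dialect$rt_unit, "second")) 60 else 1
  df <- tibble::tibble(
    a = features$mono_mass,
    b = features$abundance,
    c = features$rt_start * scale_rt,
    d = features$rt_end * scale_rt,
    e = features$rt_apex * scale_rt,
    f = features$charge_min,
    g = features$charge_max
  )
  names(df) <- unname(dialect$columns[c("mono_mass", "abundance", "rt_start",
                                        "rt_end", "rt_apex", "charge_min",
                                        "charge_max")])
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}
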