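# Plate, layout and compound-map input/output for 1536-well screens.
#
# A "plate set" is a tibble of well records, one row per well, with the
# columns documented in [plate_set()]. Both on-disk tables are plain CSV;
# coordinates may be written 0-based numeric or as A1-style labels
# (rows A..AF, columns 1..48) and are normalized to 0-based integers.

PLATE_ROWS <- 32L
PLATE_COLS <- 48L
CELL_LINES <- c("WT", "RD16", "PARENTAL")
TREATMENTS <- c("COMPOUND", "DMSO")
ASSAY_KINDS <- c("DISEASE_ASSAY", "COUNTER_SCREEN", "POSITIVE_CONTROL")

#' Construct a plate set from well records
#'
#' A plate set is the package's central container: a tibble with one row per
#' well of a 1536-well (32 x 48) screening plate, carrying both raw
#' two-channel intensities and the layout annotation needed for
#' normalization. All downstream stages (`mask_local_artifacts()`,
#' `normalize_campaign()`, `fit_campaign()`, `triage_campaign()`) consume
#' and return plain tibbles, so pipelines compose with the pipe.
#'
#' @param wells A data frame with columns `plate_id` (character), `row`
#'   (integer, 0..31), `col` (integer, 0..47), `cell_line` (one of `"WT"`,
#'   `"RD16"`, `"PARENTAL"`), `treatment` (`"COMPOUND"` or `"DMSO"`),
#'   `compound_id` (character, `NA` iff DMSO), `concentration` (mol/L, `NA`
#'   iff DMSO), `gfp` and `dapi` (non-negative intensities, channel 488 and
#'   405), `masked` (logical). Optional columns `assay_kind` (one of
#'   `"DISEASE_ASSAY"`, `"COUNTER_SCREEN"`, `"POSITIVE_CONTROL"`; inferred
#'   from the plate's compound-well cell line when absent) and `replicate`
#'   (integer >= 0, default 0).
#' @return A validated tibble of class `plate_set`.
#' @examples
#' plate_set(tibble::tibble(
#'   plate_id = "P1", row = 0:3, col = 0L,
#'   cell_line = c("WT", "WT", "RD16", "RD16"), treatment = "DMSO",
#'   compound_id = NA_character_, concentration = NA_real_,
#'   gfp = c(110, 130, 38, 42), dapi = c(900, 1100, 480, 520),
#'   masked = FALSE
#' ))
#' @export
plate_set <- function(wells) {
  wells <- as_tibble(wells)
  if (!"replicate" %in% names(wells)) wells$replicate <- 0L
  if (!"assay_kind" %in% names(wells)) wells$assay_kind <- NA_character_
  wells <- wells %>%
    mutate(
      plate_id = as.character(.data$plate_id),
      row = as.integer(.data$row),
      col = as.integer(.data$col),
      compound_id = as.character(.data$compound_id),
      concentration = as.numeric(.data$concentration),
      gfp = as.numeric(.data$gfp),
      dapi = as.numeric(.data$dapi),
      masked = as.logical(.data$masked),
      replicate = as.integer(.data$replicate)
    )
  wells$assay_kind <- infer_assay_kind(wells)
  validate_wells(wells)
  class(wells) <- c("plate_set", class(wells))
  wells
}

# Assay kind of a plate follows the cell line of its compound wells; a plate
# with no compound wells falls back to its modal cell line.
infer_assay_kind <- function(wells) {
  known <- wells$assay_kind
  per_plate <- vapply(split(seq_len(nrow(wells)), wells$plate_id), function(i) {
    kn <- unique(known[i][!is.na(known[i])])
    if (length(kn) == 1) return(kn)
    cmp <- wells$cell_line[i][wells$treatment[i] == "COMPOUND"]
    line <- if (length(cmp)) names(which.max(table(cmp))) else {
      names(which.max(table(wells$cell_line[i])))
    }
    c(WT = "POSITIVE_CONTROL", RD16 = "DISEASE_ASSAY",
      PARENTAL = "COUNTER_SCREEN")[[line]]
  }, character(1))
  unname(per_plate[wells$plate_id])
}

validate_wells <- function(wells) {
  need <- c("plate_id", "row", "col", "cell_line", "treatment", "compound_id",
            "concentration", "gfp", "dapi", "masked", "assay_kind", "replicate")
  missing <- setdiff(need, names(wells))
  if (length(missing)) {
    abort(paste0("plate set is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  bad_row <- which(is.na(wells$row) | wells$row < 0L | wells$row >= PLATE_ROWS)
  bad_col <- which(is.na(wells$col) | wells$col < 0L | wells$col >= PLATE_COLS)
  if (length(bad_row)) {
    abort(sprintf("well row out of range [0,%d) at record %d",
                  PLATE_ROWS, bad_row[1]))
  }
  if (length(bad_col)) {
    abort(sprintf("well col out of range [0,%d) at record %d",
                  PLATE_COLS, bad_col[1]))
  }
  if (!all(wells$cell_line %in% CELL_LINES)) {
    abort(paste0("cell_line must be one of ", paste(CELL_LINES, collapse = "/")))
  }
  if (!all(wells$treatment %in% TREATMENTS)) {
    abort(paste0("treatment must be one of ", paste(TREATMENTS, collapse = "/")))
  }
  dmso <- wells$treatment == "DMSO"
  if (any(dmso & (!is.na(wells$compound_id) | !is.na(wells$concentration)))) {
    abort("DMSO wells must have null compound_id and concentration")
  }
  if (any(!dmso & (is.na(wells$compound_id) | is.na(wells$concentration)))) {
    abort("compound wells must carry compound_id and concentration")
  }
  if (any(!dmso & wells$concentration <= 0, na.rm = TRUE)) {
    abort("concentrations must be positive (mol/L)")
  }
  neg <- !is.na(wells$gfp) & (wells$gfp < 0) | !is.na(wells$dapi) & (wells$dapi < 0)
  if (any(neg, na.rm = TRUE)) abort("intensities must be non-negative")
  key <- paste(wells$plate_id, wells$row, wells$col)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate well: ", key[duplicated(key)][1]))
  }
  invisible(wells)
}

# ---- coordinate dialect -----------------------------------------------------

# Row labels run A..Z, AA..AF (32 rows); columns 1..48. parse_* return
# 0-based integers and NA for unparseable input.
parse_row_label <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- suppressWarnings(as.integer(x))
  alpha <- is.na(out) & grepl("^[A-Z]{1,2}$", x)
  if (any(alpha)) {
    lab <- x[alpha]
    val <- ifelse(nchar(lab) == 1L,
                  match(lab, LETTERS) - 1L,
                  26L * match(substr(lab, 1, 1), LETTERS) +
                    match(substr(lab, 2, 2), LETTERS) - 1L)
    out[alpha] <- as.integer(val)
  }
  out
}

parse_col_label <- function(x, one_based_alpha_row) {
  # columns are numeric in both dialects; A1-style columns are 1-based
  out <- suppressWarnings(as.integer(trimws(as.character(x))))
  ifelse(one_based_alpha_row, out - 1L, out)
}

#' Convert 0-based well coordinates to an A1-style label
#'
#' @param row,col Integer vectors, 0-based (row 0..31, col 0..47).
#' @return Character labels such as `"A1"` or `"AF48"`.
#' @export
well_label <- function(row, col) {
  stopifnot(all(row >= 0 & row < PLATE_ROWS), all(col >= 0 & col < PLATE_COLS))
  paste0(c(LETTERS, paste0("A", LETTERS))[row + 1L], col + 1L)
}

# ---- readers ----------------------------------------------------------------

read_screen_csv <- function(path, what) {
  if (!file.exists(path)) abort(paste0(what, " file not found: ", path))
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

parse_coords <- function(tab, path) {
  raw_row <- tab$row
  alpha <- grepl("^[A-Za-z]", trimws(raw_row))
  row <- parse_row_label(raw_row)
  col <- parse_col_label(tab$col, alpha)
  bad <- which(is.na(row) | is.na(col) | row < 0L | row >= PLATE_ROWS |
                 col < 0L | col >= PLATE_COLS)
  if (length(bad)) {
    abort(sprintf(
      "%s: line %d: field row/col: coordinates '%s','%s' outside the 32x48 plate",
      path, bad[1] + 1L, raw_row[bad[1]], tab$col[bad[1]]))
  }
  tab$row <- row
  tab$col <- col
  tab
}

parse_num_field <- function(x, field, path, allow_na = FALSE, min = -Inf) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which((is.na(out) & !(allow_na & (is.na(x) | x == ""))) |
                 (!is.na(out) & out < min))
  if (length(bad)) {
    abort(sprintf("%s: line %d: field %s: invalid value '%s'",
                  path, bad[1] + 1L, field, x[bad[1]]))
  }
  out
}

parse_enum_field <- function(x, field, levels, path) {
  out <- toupper(trimws(x))
  bad <- which(!out %in% levels)
  if (length(bad)) {
    abort(sprintf("%s: line %d: field %s: '%s' is not one of %s",
                  path, bad[1] + 1L, field, x[bad[1]],
                  paste(levels, collapse = "/")))
  }
  out
}

#' Read a plate intensity table joined to its layout
#'
#' Joins a plate intensity CSV (`plate_id,row,col,gfp,dapi`) to a layout CSV
#' (`plate_id,row,col,cell_line,treatment,compound_id,concentration_molar,`
#' `masked`, optional `replicate`) by well coordinate. Every intensity row
#' must have a layout row; layout wells with no measured intensity are kept
#' with `masked = TRUE` so downstream stages skip them.
#'
#' @param path Path to the intensity CSV.
#' @param layout Path to the layout CSV.
#' @return A [plate_set()] tibble.
#' @export
read_plate_table <- function(path, layout) {
  ints <- read_screen_csv(path, "plate table")
  lay <- read_screen_csv(layout, "layout")
  need_i <- c("plate_id", "row", "col", "gfp", "dapi")
  need_l <- c("plate_id", "row", "col", "cell_line", "treatment",
              "compound_id", "concentration_molar", "masked")
  if (!all(need_i %in% names(ints))) {
    abort(paste0(path, ": header must contain ", paste(need_i, collapse = ",")))
  }
  if (!all(need_l %in% names(lay))) {
    abort(paste0(layout, ": header must contain ", paste(need_l, collapse = ",")))
  }
  ints <- parse_coords(ints, path)
  lay <- parse_coords(lay, layout)
  ints$gfp <- parse_num_field(ints$gfp, "gfp", path, min = 0)
  ints$dapi <- parse_num_field(ints$dapi, "dapi", path, min = 0)
  lay$cell_line <- parse_enum_field(lay$cell_line, "cell_line", CELL_LINES, layout)
  lay$treatment <- parse_enum_field(lay$treatment, "treatment", TREATMENTS, layout)
  lay$concentration <- parse_num_field(lay$concentration_molar,
                                       "concentration_molar", layout,
                                       allow_na = TRUE, min = 0)
  lay$masked <- parse_enum_field(lay$masked, "masked",
                                 c("TRUE", "FALSE"), layout) == "TRUE"
  lay$compound_id <- ifelse(is.na(lay$compound_id) | lay$compound_id == "",
                            NA_character_, lay$compound_id)
  lay$replicate <- if ("replicate" %in% names(lay)) {
    as.integer(parse_num_field(lay$replicate, "replicate", layout, min = 0))
  } else 0L
  for (tab in list(ints, lay)) {
    key <- paste(tab$plate_id, tab$row, tab$col)
    if (anyDuplicated(key)) {
      abort(paste0("duplicate well ", key[duplicated(key)][1],
                   " in ", if (identical(tab, ints)) path else layout))
    }
  }
  joined <- lay %>%
    select("plate_id", "row", "col", "cell_line", "treatment", "compound_id",
           "concentration", "masked", "replicate") %>%
    left_join(ints %>% select("plate_id", "row", "col", "gfp", "dapi"),
              by = c("plate_id", "row", "col"))
  orphan <- anti_join(ints, lay, by = c("plate_id", "row", "col"))
  if (nrow(orphan)) {
    abort(sprintf("%s: intensity well %s/%s has no layout row", path,
                  orphan$plate_id[1],
                  well_label(orphan$row[1], orphan$col[1])))
  }
  # layout-only wells: no measurement -> masked placeholder
  unmeasured <- is.na(joined$gfp) & is.na(joined$dapi)
  joined$masked <- joined$masked | unmeasured
  joined$gfp[unmeasured] <- 0
  joined$dapi[unmeasured] <- 0
  plate_set(joined)
}

#' Write a plate set as intensity + layout CSVs
#'
#' Inverse of [read_plate_table()]: `read_plate_table()` on the two files
#' written here reproduces the plate set field-for-field.
#'
#' @param plates A [plate_set()] tibble.
#' @param path Output path for the intensity CSV.
#' @param layout Output path for the layout CSV.
#' @param header_lines Optional `#`-prefixed comment lines written atop both
#'   files (used by the pipeline to stamp the config hash).
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(plates, path,
                              layout = sub("\\.csv$", "_layout.csv", path),
                              header_lines = character()) {
  validate_wells(plates)
  ord <- order(plates$plate_id, plates$row, plates$col)
  plates <- plates[ord, ]
  ints <- plates %>% select("plate_id", "row", "col", "gfp", "dapi")
  lay <- plates %>%
    mutate(concentration_molar = .data$concentration,
           masked = ifelse(.data$masked, "true", "false")) %>%
    select("plate_id", "row", "col", "cell_line", "treatment", "compound_id",
           "concentration_molar", "masked", "replicate")
  write_csv_commented(ints, path, header_lines)
  write_csv_commented(lay, layout, header_lines)
  invisible(path)
}

write_csv_commented <- function(tab, path, header_lines = character()) {
  txt <- readr::format_csv(tab)
  writeLines(c(header_lines, sub("\n$", "", txt)), path)
  invisible(path)
}

#' Serial dilution series
#'
#' Concentrations of an n-point serial dilution: `stock, stock/factor, ...,`
#' `stock/factor^(n_points-1)` (mol/L), the layout used by the screens this
#' package models (1:3 from a 10 mM stock; seven points in the primary
#' screen, eleven in the confirmatory screen).
#'
#' @param stock Starting concentration, mol/L. Must be positive.
#' @param factor Dilution factor between adjacent points, > 1.
#' @param n_points Number of concentrations, >= 1.
#' @return Numeric vector of length `n_points`, strictly decreasing.
#' @examples
#' dilution_series(1e-2, 3, 7)
#' @export
dilution_series <- function(stock, factor = 3, n_points = 7L) {
  if (!is.numeric(stock) || length(stock) != 1L || stock <= 0) {
    abort("stock must be a single positive concentration (mol/L)")
  }
  if (!is.numeric(factor) || factor <= 1) abort("dilution factor must be > 1")
  if (n_points < 1) abort("n_points must be >= 1")
  stock / factor^(seq_len(n_points) - 1)
}

#' Read a compound map CSV
#'
#' @param path CSV with header `compound_id,name,stock_molar`.
#' @return Tibble with those columns; `stock_molar` numeric (mol/L).
#' @export
read_compound_map <- function(path) {
  tab <- read_screen_csv(path, "compound map")
  need <- c("compound_id", "name", "stock_molar")
  if (!all(need %in% names(tab))) {
    abort(paste0(path, ": header must contain ", paste(need, collapse = ",")))
  }
  tab$stock_molar <- parse_num_field(tab$stock_molar, "stock_molar", path, min = 0)
  as_tibble(tab[need])
}
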