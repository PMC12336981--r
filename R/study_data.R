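#' The six model descriptors
#'
#' Descriptor labels used by the activity models, in canonical order:
#' stretch energy `S` (kcal/mol), torsion energy `Tor` (kcal/mol), melting
#' point `MP`, rotatable-bond count `NRB`, repulsion energy `repul`, and
#' hardness `eta` (Hartree, half the HOMO-LUMO gap).
#'
#' @return Character vector of length six.
#' @export
qsar_terms <- function() {
  c("S", "Tor", "MP", "NRB", "repul", "eta")
}

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "mcf7qsar")
  if (!nzchar(path)) stop("fixture file not found: ", file, call. = FALSE)
  path
}

#' Load the embedded inhibitor study dataset
#'
#' Reads the packaged study tables for the 33 dihydropteridone-oxadiazole
#' MCF-7 inhibitors: the full 33-compound descriptor panel, the 31-compound
#' modeling table (25 training + 6 test rows, with observed pIC50 and the
#' published linear and polynomial model predictions), the external test-set
#' observed/predicted pairs, the five designed candidate compounds M1-M5
#' with their descriptors, and the candidates' physicochemical property rows
#' used for drug-likeness screening.
#'
#' Fixture integrity is verified against a packaged checksum manifest and a
#' set of structural invariants (split sizes, positivity of energies,
#' hardness consistent with the orbital gap) before the dataset is returned.
#'
#' @param check_integrity Verify file checksums against the manifest and run
#'   all dataset invariants. Default `TRUE`.
#' @return An object of class `study_dataset`: a list with elements
#'   `modeling` (31-row data frame keyed by modeling-table row order, with a
#'   `split` column of `"train"`/`"test"`), `panel` (33-row extended
#'   descriptor panel), `test_pairs` (6-row observed/predicted pairs),
#'   `candidates` (5-row designed compounds), `candidate_properties` (5-row
#'   drug-likeness properties) and `manifest` (fixture metadata).
#' @examples
#' ds <- load_study_dataset()
#' nrow(ds$modeling)
#' subset(ds$modeling, split == "test")$compound_id
#' @export
load_study_dataset <- function(check_integrity = TRUE) {
  manifest <- jsonlite::read_json(fixture_path("manifest.json"), simplifyVector = TRUE)

  if (check_integrity) {
    for (f in names(manifest$md5)) {
      got <- unname(tools::md5sum(fixture_path(f)))
      if (!identical(got, manifest$md5[[f]])) {
        stop("fixture integrity failure: checksum mismatch for ", f, call. = FALSE)
      }
    }
  }

  read_fix <- function(f) utils::read.csv(fixture_path(f), stringsAsFactors = FALSE)

  ds <- structure(list(
    modeling             = read_fix("table3_modeling.csv"),
    panel                = read_fix("table2_panel.csv"),
    test_pairs           = read_fix("table5_test_pairs.csv"),
    candidates           = read_fix("table7_candidates.csv"),
    candidate_properties = read_fix("table8_properties.csv"),
    manifest             = manifest
  ), class = "study_dataset")
  ds$modeling$compound_id <- as.character(ds$modeling$compound_id)
  ds$panel$compound_id <- as.character(ds$panel$compound_id)
  ds$test_pairs$compound_id <- as.character(ds$test_pairs$compound_id)

  if (check_integrity) validate_study_dataset(ds)
  ds
}

#' Validate study-dataset invariants
#'
#' Checks the structural and numerical invariants the rest of the package
#' relies on: 25 train / 6 test rows with the test rows at modeling-table
#' positions 3, 4, 12, 21, 24 and 29; five candidates labelled M1-M5;
#' positive energies and hardness with integer non-negative rotatable-bond
#' counts; `E_HOMO < E_LUMO` with the stored hardness equal to half the
#' orbital gap within 1e-4; and observed-minus-predicted consistent with the
#' tabulated residuals within 0.01.
#'
#' @param ds A `study_dataset`.
#' @return Invisibly `TRUE`; stops with a descriptive error on violation.
#' @export
validate_study_dataset <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  m <- ds$modeling
  fail <- function(...) stop("fixture integrity failure: ", ..., call. = FALSE)

  if (nrow(m) != 31L) fail("modeling table must have 31 rows")
  if (sum(m$split == "train") != 25L || sum(m$split == "test") != 6L) {
    fail("modeling split must be 25 train / 6 test")
  }
  if (!identical(which(m$split == "test"), c(3L, 4L, 12L, 21L, 24L, 29L))) {
    fail("test rows must sit at modeling-table positions 3, 4, 12, 21, 24, 29")
  }
  if (!identical(ds$candidates$compound_id, paste0("M", 1:5))) {
    fail("candidates must be the five designed compounds M1..M5")
  }

  for (tab in list(m, ds$candidates)) {
    if (any(tab$S <= 0) || any(tab$repul <= 0) || any(tab$eta <= 0)) {
      fail("S, repul and eta must be positive")
    }
    if (any(tab$NRB < 0) || any(tab$NRB != round(tab$NRB))) {
      fail("NRB must be a non-negative integer")
    }
  }
  if (any(!is.finite(m$pIC50_obs))) fail("observed activity missing in modeling table")

  p <- ds$panel
  if (nrow(p) != 33L) fail("descriptor panel must have 33 rows")
  if (any(p$E_HOMO >= p$E_LUMO)) fail("panel must satisfy E_HOMO < E_LUMO")
  if (max(abs(p$eta - (p$E_LUMO - p$E_HOMO) / 2)) > 1e-4) {
    fail("stored hardness must equal half the orbital gap within 1e-4")
  }

  if (max(abs((m$pIC50_obs - m$pIC50_pred_mlr) - m$resid_mlr)) > 0.01) {
    fail("tabulated MLR residuals inconsistent with observed - predicted")
  }
  if (max(abs((m$pIC50_obs - m$pIC50_pred_mnlr) - m$resid_mnlr)) > 0.01) {
    fail("tabulated MNLR residuals inconsistent with observed - predicted")
  }
  invisible(TRUE)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("MCF-7 inhibitor QSAR study dataset\n")
  cat(sprintf("  descriptor panel : %d compounds\n", nrow(x$panel)))
  cat(sprintf("  modeling table   : %d compounds (%d train, %d test)\n",
              nrow(x$modeling), sum(x$modeling$split == "train"),
              sum(x$modeling$split == "test")))
  cat(sprintf("  candidates       : %s\n",
              paste(x$candidates$compound_id, collapse = ", ")))
  invisible(x)
}

# --- compound-record CSV dialect ------------------------------------------
# Core columns: compound_id,S,Tor,MP,NRB,repul,eta,pIC50_obs,split
# (comma separator, decimal point, UTF-8). pIC50_obs may be NA for
# candidate rows; split is one of train/test/candidate.

compound_columns <- c("compound_id", qsar_terms(), "pIC50_obs", "split")

#' Write and read compound records in the package CSV dialect
#'
#' `write_compound_csv()` serializes the nine core columns
#' (`compound_id,S,Tor,MP,NRB,repul,eta,pIC50_obs,split`) at full double
#' precision; `read_compound_csv()` reads them back, so that a round trip
#' reproduces the records exactly.
#'
#' @param records Data frame carrying at least the core columns
#'   (`pIC50_obs` and `split` are filled with `NA`/`"train"` if absent).
#' @param path File path.
#' @return `read_compound_csv()` returns a data frame with the core columns.
#' @export
write_compound_csv <- function(records, path) {
  if (!"pIC50_obs" %in% names(records)) records$pIC50_obs <- NA_real_
  if (!"split" %in% names(records)) records$split <- "train"
  missing <- setdiff(compound_columns, names(records))
  if (length(missing)) {
    stop("records lack required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- records[, compound_columns]
  # format() would round; write full precision via as.character on doubles
  for (col in c(qsar_terms(), "pIC50_obs")) {
    out[[col]] <- vapply(out[[col]], function(v) {
      if (is.na(v)) "" else sprintf("%.17g", v)
    }, character(1))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_compound_csv
#' @export
read_compound_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(compound_id = "character"))
  missing <- setdiff(compound_columns, names(df))
  if (length(missing)) {
    stop("compound CSV lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$NRB <- as.integer(df$NRB)
  df
}
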