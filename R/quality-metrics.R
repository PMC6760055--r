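#' Saponin index labels
#'
#' The five monitored saponins, in the index order used throughout the
#' package: notoginsenoside R1, ginsenosides Rg1, Re, Rb1, Rd.
#'
#' @return Character vector of length 5.
#' @export
saponin_names <- function() {
  c("notoginsenoside_R1", "ginsenoside_Rg1", "ginsenoside_Re",
    "ginsenoside_Rb1", "ginsenoside_Rd")
}

#' Measurement record for a pooled ethanol extract
#'
#' Describes the combined (pooled) extract obtained from one lot of
#' *Panax notoginseng*: masses, dry-matter concentration and the five
#' saponin concentrations. Two sequential extractions are represented as a
#' single mass-pooled record, since the extracts are combined before
#' analysis.
#'
#' @param material_mass Mass of raw material extracted, g.
#' @param extract_mass Mass of the combined extract, g.
#' @param dry_matter_conc Dry-matter concentration of the extract, g/g
#'   (mass fraction, between 0 and 1).
#' @param saponin_conc Numeric vector of length 5: saponin concentrations in
#'   the extract, mg/g, in the order of [saponin_names()].
#'
#' @return An object of class `extraction_record`.
#' @examples
#' rec <- extraction_record(100, 500, 0.06, c(3.19, 11.8, 1.47, 10.6, 2.8))
#' extractable_dry_matter(rec)
#' @export
extraction_record <- function(material_mass, extract_mass, dry_matter_conc,
                              saponin_conc) {
  stopifnot(is.numeric(material_mass), length(material_mass) == 1,
            is.numeric(extract_mass), length(extract_mass) == 1,
            is.numeric(dry_matter_conc), length(dry_matter_conc) == 1,
            is.numeric(saponin_conc), length(saponin_conc) == 5)
  if (material_mass <= 0)
    stop("material_mass must be positive", call. = FALSE)
  if (extract_mass <= 0)
    stop("extract_mass must be positive", call. = FALSE)
  if (dry_matter_conc < 0 || dry_matter_conc > 1)
    stop("dry_matter_conc must be a mass fraction in [0, 1]", call. = FALSE)
  if (any(saponin_conc < 0))
    stop("saponin concentrations must be non-negative", call. = FALSE)
  # saponins are part of the dry matter: sum (as g/g) cannot exceed it
  if (sum(saponin_conc) / 1000 > dry_matter_conc + 1e-12)
    stop("total saponin concentration exceeds dry-matter concentration",
         call. = FALSE)
  structure(
    list(material_mass = material_mass, extract_mass = extract_mass,
         dry_matter_conc = dry_matter_conc,
         saponin_conc = stats::setNames(saponin_conc, saponin_names())),
    class = "extraction_record")
}

#' Measurement record for a chromatography eluate
#'
#' Same fields as [extraction_record()], but describing the eluate collected
#' from the resin column for one manufacturing run.
#'
#' @param material_mass Mass of raw material behind the run, g.
#' @param eluate_mass Mass of collected eluate, g.
#' @param dry_matter_conc Dry-matter concentration of the eluate, g/g.
#' @param saponin_conc Length-5 numeric, saponin concentrations mg/g.
#'
#' @return An object of class `eluate_record`.
#' @export
eluate_record <- function(material_mass, eluate_mass, dry_matter_conc,
                          saponin_conc) {
  rec <- extraction_record(material_mass, eluate_mass, dry_matter_conc,
                           saponin_conc)
  names(rec)[names(rec) == "extract_mass"] <- "eluate_mass"
  class(rec) <- "eluate_record"
  rec
}

#' Extractable dry matter content of a material lot
#'
#' The dry matter recoverable from 1 g of raw material under the
#' standardized 80% ethanol reflux protocol:
#' `EDM = M_extract * DM_extract / M_material`, reported in mg per g of
#' material. This is the Z6 material quality attribute.
#'
#' @param rec An [extraction_record()].
#' @return Extractable dry matter, mg/g material.
#' @export
extractable_dry_matter <- function(rec) {
  stopifnot(inherits(rec, "extraction_record"))
  1000 * rec$extract_mass * rec$dry_matter_conc / rec$material_mass
}

#' Extractable saponin content of a material lot
#'
#' `ES_i = M_extract * SC_i / M_material` in mg/g material; the Z1..Z5
#' material quality attributes for i = 1..5.
#'
#' @param rec An [extraction_record()].
#' @param i Saponin index 1..5 (order of [saponin_names()]); may be a vector.
#' @return Extractable content(s), mg/g material.
#' @export
extractable_saponin_content <- function(rec, i) {
  stopifnot(inherits(rec, "extraction_record"))
  if (any(i < 1 | i > 5 | i != round(i)))
    stop("saponin index must be an integer in 1..5", call. = FALSE)
  unname(rec$extract_mass * rec$saponin_conc[i] / rec$material_mass)
}

#' Material quality attributes from an extraction record
#'
#' Convenience wrapper returning the full attribute vector Z1..Z6 (five
#' extractable saponin contents plus extractable dry matter, all mg/g).
#'
#' @param rec An [extraction_record()].
#' @param batch_id Optional batch label.
#' @return A one-row data.frame with columns `batch_id`, `Z1`..`Z6`.
#' @export
material_attributes <- function(rec, batch_id = NA_character_) {
  z <- c(extractable_saponin_content(rec, 1:5), extractable_dry_matter(rec))
  out <- data.frame(batch_id = batch_id, t(z))
  names(out) <- c("batch_id", paste0("Z", 1:6))
  out
}

#' Process quality attributes of an eluate
#'
#' Computes, from one run's eluate record:
#' * `TSC`  total saponin concentration, mg/g eluate (sum of the five);
#' * `TSY`  total saponin yield, mg per g material;
#' * `DMY`  dry matter yield, mg per g material;
#' * `SP`   the five saponin purities, dimensionless fractions
#'          (saponin concentration over dry-matter concentration);
#' * `TSP`  total saponin purity, the sum of the `SP`.
#'
#' Purities are stored as fractions; multiply by 100 for percent.
#' `TSY = TSP * DMY` holds by construction.
#'
#' @param rec An [eluate_record()].
#' @return An object of class `eluate_quality`: a list with elements `SP`
#'   (length-5 named fraction vector), `TSP`, `TSC`, `TSY`, `DMY`.
#' @export
eluate_quality <- function(rec) {
  stopifnot(inherits(rec, "eluate_record"))
  if (rec$dry_matter_conc == 0 && any(rec$saponin_conc > 0))
    stop("zero dry-matter concentration with nonzero saponins", call. = FALSE)
  tsc <- sum(rec$saponin_conc)
  tsy <- rec$eluate_mass * tsc / rec$material_mass
  dmy <- 1000 * rec$eluate_mass * rec$dry_matter_conc / rec$material_mass
  # mg/g over (g/g expressed as mg/g) -> fraction
  sp <- if (rec$dry_matter_conc > 0)
    rec$saponin_conc / (1000 * rec$dry_matter_conc)
  else stats::setNames(numeric(5), saponin_names())
  structure(list(SP = sp, TSP = sum(sp), TSC = tsc, TSY = tsy, DMY = dmy),
            class = "eluate_quality")
}

#' @export
print.eluate_quality <- function(x, ...) {
  cat("Eluate process quality attributes\n")
  cat(sprintf("  saponin purities (%%): %s\n",
              paste(sprintf("%.2f", 100 * x$SP), collapse = ", ")))
  cat(sprintf("  total saponin purity: %.2f %%\n", 100 * x$TSP))
  cat(sprintf("  TSC %.1f mg/g eluate; TSY %.1f, DMY %.1f mg/g material\n",
              x$TSC, x$TSY, x$DMY))
  invisible(x)
}
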