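# Closed vocabularies for claw lesions, DD stages and culling reasons,
# plus the classification predicates used by the KPI module.

.clawbench <- new.env(parent = emptyenv())

#' Claw-lesion code vocabulary
#'
#' Returns the lesion-code table shipped with the package. The vocabulary is a
#' synthetic reconstruction in the style of the ICAR Claw Health Atlas: 23
#' Atlas-style lesion entries, the six digital-dermatitis M-stages of
#' Appendix 1 (`M0` ... `M4.1`), DD-associated claw horn lesions in the style
#' of Appendix 2 (`SU-DD`, `BU-DD`, `WL-DD`), a distinct code `HF-P` for
#' penetrating infected horn fissures, and the explicit no-lesion code `NL`
#' used to document lesion-free trimmings.
#'
#' @details Columns:
#' \describe{
#'   \item{code}{short stable identifier used in trimming records.}
#'   \item{name}{display name.}
#'   \item{group}{one of the 13 benchmark lesion groups (see
#'     [benchmark_groups()]), `"other"` for Atlas lesions outside the 13, or
#'     `NA` for non-lesion codes (`M0`, `NL`). White-line disease carries
#'     group `WLD` here; analysis records of severity 2-3 are regrouped to
#'     `WLA` (white line abscess) by [lesion_group()].}
#'   \item{atlas}{entry belongs to the 23-lesion Atlas core list.}
#'   \item{is_lesion}{`FALSE` for healthy-skin/no-lesion codes.}
#'   \item{alarm_rule}{`"always"`, `"sev2plus"` (white line disease) or
#'     `"none"`; drives [is_alarm()].}
#'   \item{dd_associated}{DD-associated claw horn lesion (Appendix-2 style);
#'     always an alarm lesion.}
#'   \item{severity_sensitive}{severity-1 records of this code from trimmers
#'     are dropped before KPI computation (sole haemorrhage, double sole,
#'     white line disease, heel horn erosion).}
#' }
#'
#' @return A data.frame, one row per code.
#' @export
#' @examples
#' head(claw_lesion_codes())
claw_lesion_codes <- function() {
  if (is.null(.clawbench$vocab)) {
    path <- system.file("extdata", "lesion_codes.csv", package = "clawbench")
    v <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = character())
    for (col in c("atlas", "is_lesion", "dd_associated", "severity_sensitive"))
      v[[col]] <- as.logical(v[[col]])
    v$group[v$group == ""] <- NA_character_
    .clawbench$vocab <- v
  }
  .clawbench$vocab
}

#' The 13 benchmark lesion groups
#'
#' Group identifiers of the 13 claw-lesion categories benchmarked at herd
#' level: thin sole (TS), interdigital phlegmon (IP), swelling of
#' coronet/bulb (SW), horn fissure (HF), interdigital hyperplasia (IH),
#' double sole (DS), corkscrew claw (CC), heel horn erosion (HHE), sole
#' haemorrhage (SH), white line abscess (WLA), ulcers incl. toe necrosis
#' (UL), concave dorsal wall (CD) and digital dermatitis (DD).
#'
#' @return Character vector of length 13.
#' @export
benchmark_groups <- function() {
  c("TS", "IP", "SW", "HF", "IH", "DS", "CC", "HHE",
    "SH", "WLA", "UL", "CD", "DD")
}

#' The six digital-dermatitis M-stages
#' @return Character vector `M0` ... `M4.1`.
#' @export
dd_stages <- function() c("M0", "M1", "M2", "M3", "M4", "M4.1")

#' Coded culling reasons
#'
#' The ten culling reasons used in culling records; `"claw_limb"` marks culls
#' directly due to claw and limb disorders.
#' @return Character vector of length 10.
#' @export
culling_reasons <- function() {
  c("claw_limb", "udder_mastitis", "infertility", "low_yield",
    "metabolic_disease", "other_disease", "accident_injury", "age",
    "sold_breeding", "death")
}

# match codes against the vocabulary, failing loudly on unknown codes
resolve_codes <- function(code) {
  v <- claw_lesion_codes()
  i <- match(code, v$code)
  if (anyNA(i)) {
    bad <- unique(code[is.na(i)])
    stop("unknown lesion code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  i
}

#' Lesion group of a trimming record
#'
#' Maps lesion codes (plus severity, where it matters) to the 13 benchmark
#' groups. White line disease of severity 2-3 is regrouped as white line
#' abscess (`WLA`); all DD stages `M1`-`M4.1` map to `DD`; non-lesion codes
#' (`M0`, `NL`) map to `NA`.
#'
#' @param code character vector of lesion codes.
#' @param severity integer severity scores 1-3, or `NA` (recycled).
#' @return Character vector: a group of [benchmark_groups()], `"other"`,
#'   `"WLD"` (severity-1/unknown white line disease) or `NA`.
#' @export
#' @examples
#' lesion_group(c("BU", "WLD", "WLD", "M2", "NL"), c(2, 2, 1, NA, NA))
lesion_group <- function(code, severity = NA) {
  i <- resolve_codes(code)
  v <- claw_lesion_codes()
  g <- v$group[i]
  sev <- suppressWarnings(as.numeric(rep_len(severity, length(code))))
  g[g %in% "WLD" & !is.na(sev) & sev >= 2] <- "WLA"
  g
}

#' Is a record a painful 'alarm' lesion?
#'
#' Alarm lesions are the claw disorders regarded as always painful: all
#' ulcers (sole, toe, bulb) and toe necrosis, white line abscesses (white
#' line disease of severity 2-3), inflammatory swellings of coronet/bulb,
#' interdigital phlegmon, penetrating infected horn fissures, acute (M2)
#' digital dermatitis, and all DD-associated claw horn lesions.
#'
#' @inheritParams lesion_group
#' @return Logical vector.
#' @export
#' @examples
#' is_alarm(c("SU", "M4", "NL", "WLD", "WLD"), c(3, NA, NA, 1, 2))
is_alarm <- function(code, severity = NA) {
  i <- resolve_codes(code)
  v <- claw_lesion_codes()
  rule <- v$alarm_rule[i]
  sev <- suppressWarnings(as.numeric(rep_len(severity, length(code))))
  rule == "always" | (rule == "sev2plus" & !is.na(sev) & sev >= 2)
}
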