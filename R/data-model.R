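#' Quasi-taxonomic groups
#'
#' The seven pooled taxon sets used as exchangeable units throughout the
#' analyses. Orders or classes are pooled where species-level salinity
#' tolerances are broadly similar, which keeps per-group sample sizes workable.
#'
#' @return Character vector of the seven group names.
#' @export
#' @examples
#' quasi_groups()
quasi_groups <- function() {
  c(
    "Coleoptera & Odonata", "Crustaceans", "Diptera & Hemiptera",
    "Ephemeroptera", "Hydracarina", "Non-arthropods",
    "Trichoptera & Plecoptera"
  )
}

# order/class -> quasi-group lookup; group names map to themselves so that
# synthetic tables round-trip. Lepidoptera and Megaloptera are deliberately
# absent: each was tested as a single species and is never assigned to a
# pooled group, so they stay unmapped (NA) and drop out of group analyses.
.group_lookup <- local({
  m <- c(
    "coleoptera" = "Coleoptera & Odonata",
    "odonata" = "Coleoptera & Odonata",
    "crustacea" = "Crustaceans",
    "crustaceans" = "Crustaceans",
    "malacostraca" = "Crustaceans",
    "amphipoda" = "Crustaceans",
    "decapoda" = "Crustaceans",
    "isopoda" = "Crustaceans",
    "mysida" = "Crustaceans",
    "diptera" = "Diptera & Hemiptera",
    "hemiptera" = "Diptera & Hemiptera",
    "ephemeroptera" = "Ephemeroptera",
    "hydracarina" = "Hydracarina",
    "acarina" = "Hydracarina",
    "trombidiformes" = "Hydracarina",
    "annelida" = "Non-arthropods",
    "oligochaeta" = "Non-arthropods",
    "hirudinea" = "Non-arthropods",
    "mollusca" = "Non-arthropods",
    "gastropoda" = "Non-arthropods",
    "bivalvia" = "Non-arthropods",
    "platyhelminthes" = "Non-arthropods",
    "turbellaria" = "Non-arthropods",
    "tricladida" = "Non-arthropods",
    "trichoptera" = "Trichoptera & Plecoptera",
    "plecoptera" = "Trichoptera & Plecoptera"
  )
  g <- quasi_groups()
  names(g) <- tolower(g)
  c(m, g)
})

# orders known to the data model that carry no group (single-species orders)
.known_unmapped <- c("lepidoptera", "megaloptera")

#' Map an order or class name to its quasi-taxonomic group
#'
#' @param order_or_class Character vector of order/class names (e.g.
#'   `"Ephemeroptera"`, `"Mollusca"`). Matching is case-insensitive.
#' @param strict If `TRUE` (default), names absent from the lookup raise an
#'   error listing them. Lepidoptera and Megaloptera are recognised but
#'   unmapped: they return `NA` and are excluded from group-level analyses.
#' @return Character vector of group names (see [quasi_groups()]), `NA` for
#'   recognised-but-unmapped orders.
#' @export
#' @examples
#' assign_quasi_group(c("Ephemeroptera", "Mollusca", "Diptera"))
assign_quasi_group <- function(order_or_class, strict = TRUE) {
  key <- tolower(trimws(order_or_class))
  grp <- unname(.group_lookup[key])
  unknown <- !is.na(order_or_class) & is.na(grp) & !(key %in% .known_unmapped)
  if (strict && any(unknown)) {
    stop(
      "no quasi-taxonomic group mapping for order/class: ",
      paste(unique(order_or_class[unknown]), collapse = ", "),
      call. = FALSE
    )
  }
  grp
}

# normalize one numeric token: trim, decimal comma -> point
.parse_number_token <- function(token) {
  tok <- gsub(",", ".", trimws(token), fixed = TRUE)
  ok <- grepl("^[0-9]+\\.?[0-9]*$|^\\.[0-9]+$", tok)
  out <- rep(NA_real_, length(tok))
  out[ok] <- as.numeric(tok[ok])
  bad <- !ok | !is.finite(out)
  if (any(bad)) {
    stop("unparseable LC50 number: '", token[bad][1], "'", call. = FALSE)
  }
  if (any(out <= 0)) {
    stop("non-positive LC50 bound: '", token[out <= 0][1], "'", call. = FALSE)
  }
  out
}

#' Parse censored LC50 notation
#'
#' Toxicity tables record a 72-h LC50 either as a point value (`"12.6"`), an
#' interval between two tested concentrations (`"35-40"`, also en-dash or
#' minus-sign separated), or a right-censored bound (`">30"`) when the species
#' tolerated the highest concentration tested. Decimal commas are accepted.
#'
#' @param text Character vector of LC50 values in one of the three notations.
#' @return A tibble with one row per input: `censor_kind` (`"point"`,
#'   `"interval"` or `"right"`), `lo` and `hi`. For point values `hi == lo`;
#'   for right-censored values `hi == Inf` and `lo` is the censoring bound.
#' @export
#' @examples
#' parse_lc50(c(">30", "35–40", "12.6"))
parse_lc50 <- function(text) {
  if (length(text) == 0L) {
    stop("empty LC50 value", call. = FALSE)
  }
  one <- function(x) {
    raw <- x
    x <- trimws(x)
    if (is.na(x) || !nzchar(x)) {
      stop("empty LC50 value", call. = FALSE)
    }
    if (startsWith(x, ">")) {
      lo <- .parse_number_token(sub("^>", "", x))
      return(c(kind = "right", lo = lo, hi = Inf))
    }
    parts <- strsplit(x, "[-–−]")[[1]]
    parts <- parts[nzchar(trimws(parts))]
    if (length(parts) == 1L) {
      lo <- .parse_number_token(parts)
      return(c(kind = "point", lo = lo, hi = lo))
    }
    if (length(parts) == 2L) {
      lo <- .parse_number_token(parts[1])
      hi <- .parse_number_token(parts[2])
      if (hi <= lo) {
        stop("inverted interval in LC50 value: '", raw, "'", call. = FALSE)
      }
      return(c(kind = "interval", lo = lo, hi = hi))
    }
    stop("unparseable LC50 value: '", raw, "'", call. = FALSE)
  }
  parsed <- lapply(as.character(text), one)
  tibble::tibble(
    censor_kind = vapply(parsed, `[[`, character(1), "kind"),
    lo = as.numeric(vapply(parsed, `[[`, character(1), "lo")),
    hi = as.numeric(vapply(parsed, `[[`, character(1), "hi"))
  )
}

#' Format a censoring triple back into LC50 notation
#'
#' Inverse of [parse_lc50()]: `"x"`, `"x-y"` (en-dash) or `">x"`.
#'
#' @param censor_kind,lo,hi Vectors as produced by [parse_lc50()].
#' @return Character vector.
#' @export
format_lc50 <- function(censor_kind, lo, hi) {
  num <- function(v) format(v, trim = TRUE, scientific = FALSE, digits = 15)
  dplyr::case_when(
    censor_kind == "right" ~ paste0(">", num(lo)),
    censor_kind == "interval" ~ paste0(num(lo), "–", num(hi)),
    TRUE ~ num(lo)
  )
}

#' Validate a toxicity-record table
#'
#' Checks the invariants of the record data model: positive bounds, ordered
#' interval endpoints, infinite upper bound exactly for right-censored rows,
#' and a recognised quasi-taxonomic group (or `NA` for the known unmapped
#' orders).
#'
#' @param records A data frame with columns `taxon`, `region`,
#'   `order_or_class`, `group`, `censor_kind`, `lo`, `hi`, `abundance`.
#' @return The validated records as a tibble, with the conductivity unit
#'   attribute set to `"mS/cm"`.
#' @export
as_toxicity_records <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("taxon", "region", "order_or_class", "group", "censor_kind", "lo", "hi", "abundance")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("missing record columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(records$censor_kind %in% c("point", "interval", "right"))) {
    stop("censor_kind must be point, interval or right", call. = FALSE)
  }
  if (any(!is.finite(records$lo) | records$lo <= 0)) {
    stop("lo must be positive and finite", call. = FALSE)
  }
  kind <- records$censor_kind
  if (any(kind == "point" & records$hi != records$lo)) {
    stop("point records must have hi == lo", call. = FALSE)
  }
  if (any(kind == "interval" & records$hi <= records$lo)) {
    stop("interval records must have hi > lo", call. = FALSE)
  }
  if (any(kind == "right" & is.finite(records$hi))) {
    stop("right-censored records must have hi == Inf", call. = FALSE)
  }
  bad_grp <- !is.na(records$group) & !(records$group %in% quasi_groups())
  if (any(bad_grp)) {
    stop(
      "unrecognised quasi-taxonomic group: ",
      paste(unique(records$group[bad_grp]), collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(records$abundance %in% c("rare", "abundant", "unknown"))) {
    stop("abundance must be rare, abundant or unknown", call. = FALSE)
  }
  attr(records, "unit") <- "mS/cm"
  records
}

#' Read a censored toxicity CSV
#'
#' Reads a table of 72-h LC50 records with columns `taxon`, `region`,
#' `order_or_class`, `lc50` and optionally `abundance`. The `lc50` column may
#' use any of the three notations understood by [parse_lc50()]. Values
#' recorded in uS/cm (electrical conductivity at 25 degrees C) are divided by
#' 1000; everything downstream works in mS/cm. Each row is assigned its
#' quasi-taxonomic group from `order_or_class`; unknown orders are an error,
#' while the recognised single-species orders (Lepidoptera, Megaloptera)
#' get `NA` and are excluded from group analyses.
#'
#' Duplicate taxon names within one region keep the first row with a warning.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param unit Unit of the `lc50` column: `"mS/cm"` (default) or `"uS/cm"`
#'   (also accepted spelled with a micro sign).
#' @return A tibble of toxicity records (see [as_toxicity_records()]), in
#'   mS/cm.
#' @export
read_toxicity_csv <- function(path, unit = c("mS/cm", "uS/cm")) {
  unit <- sub("^µ", "u", unit[1])
  unit <- match.arg(unit, c("mS/cm", "uS/cm"))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("taxon", "region", "order_or_class", "lc50")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("missing CSV columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  parsed <- parse_lc50(raw$lc50)
  if (identical(unit, "uS/cm")) {
    parsed$lo <- parsed$lo / 1000
    parsed$hi <- parsed$hi / 1000
  }
  abundance <- if ("abundance" %in% names(raw)) {
    tolower(ifelse(is.na(raw$abundance) | !nzchar(raw$abundance), "unknown", raw$abundance))
  } else {
    rep("unknown", nrow(raw))
  }
  records <- tibble::tibble(
    taxon = raw$taxon,
    region = raw$region,
    order_or_class = raw$order_or_class,
    group = assign_quasi_group(raw$order_or_class),
    censor_kind = parsed$censor_kind,
    lo = parsed$lo,
    hi = parsed$hi,
    abundance = abundance
  )
  dup <- duplicated(records[, c("region", "taxon")])
  if (any(dup)) {
    warning(
      "duplicate taxon within region, keeping first occurrence: ",
      paste(unique(records$taxon[dup]), collapse = ", "),
      call. = FALSE
    )
    records <- records[!dup, ]
  }
  as_toxicity_records(records)
}

#' Write toxicity records to CSV
#'
#' Writes records in the same layout [read_toxicity_csv()] reads (always in
#' mS/cm), so that a write/read round trip reproduces the censoring triples
#' exactly.
#'
#' @param records A toxicity-record tibble.
#' @param path Output path.
#' @return `records`, invisibly.
#' @export
write_toxicity_csv <- function(records, path) {
  records <- as_toxicity_records(records)
  out <- tibble::tibble(
    taxon = records$taxon,
    region = records$region,
    order_or_class = records$order_or_class,
    lc50 = format_lc50(records$censor_kind, records$lo, records$hi),
    abundance = records$abundance
  )
  readr::write_csv(out, path)
  invisible(records)
}

#' Collapse duplicate taxa to one record each
#'
#' When regional datasets are pooled, a taxon tested in more than one place
#' must contribute a single 72-h LC50. The more informative (narrower)
#' censoring wins: a point beats an interval beats a right-censored bound, and
#' among intervals the narrower one is kept. Ties are broken towards the
#' smaller midpoint (the censoring bound itself for right-censored records).
#'
#' @param records A toxicity-record tibble, possibly with repeated `taxon`
#'   values across regions.
#' @return A tibble with one row per taxon.
#' @export
#' @examples
#' recs <- as_toxicity_records(tibble::tibble(
#'   taxon = c("sp1", "sp1"), region = c("A", "B"),
#'   order_or_class = "Ephemeroptera", group = "Ephemeroptera",
#'   censor_kind = c("right", "interval"), lo = c(30, 35), hi = c(Inf, 40),
#'   abundance = "unknown"
#' ))
#' merge_duplicate_taxa(recs)
merge_duplicate_taxa <- function(records) {
  records <- as_toxicity_records(records)
  width <- records$hi - records$lo
  mid <- ifelse(records$censor_kind == "right", records$lo, (records$lo + records$hi) / 2)
  out <- records |>
    dplyr::mutate(.width = width, .mid = mid) |>
    dplyr::group_by(.data$taxon) |>
    dplyr::arrange(.data$.width, .data$.mid, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select(-".width", -".mid")
  as_toxicity_records(out)
}

#' Normalised regional species-richness weights
#'
#' Ecological weights used to mix quasi-taxonomic group SSDs into an
#' assemblage SSD: each group's share of the regional species richness.
#'
#' @param weights A named numeric vector (names are quasi-taxonomic groups) of
#'   species counts or fractions, or a data frame with columns `group` and
#'   `weight` (a `count` column is also accepted).
#' @param region Label for the region the weights describe.
#' @return A tibble with columns `group` and `weight`, weights non-negative
#'   and summing to one, with a `region` attribute.
#' @export
#' @examples
#' regional_weights(c("Ephemeroptera" = 30, "Crustaceans" = 70), region = "toy")
regional_weights <- function(weights, region = "unspecified") {
  if (is.data.frame(weights)) {
    wcol <- if ("weight" %in% names(weights)) "weight" else "count"
    if (!all(c("group", wcol) %in% names(weights))) {
      stop("weights data frame needs columns group and weight (or count)", call. = FALSE)
    }
    w <- stats::setNames(as.numeric(weights[[wcol]]), weights$group)
  } else {
    w <- weights
  }
  if (is.null(names(w)) || any(!nzchar(names(w)))) {
    stop("weights must be named by quasi-taxonomic group", call. = FALSE)
  }
  bad <- !(names(w) %in% quasi_groups())
  if (any(bad)) {
    stop("unknown group in weights: ", paste(names(w)[bad], collapse = ", "), call. = FALSE)
  }
  if (any(w < 0) || sum(w) <= 0) {
    stop("weights must be non-negative with a positive sum", call. = FALSE)
  }
  w <- w / sum(w)
  stopifnot(abs(sum(w) - 1) < 1e-9)
  out <- tibble::tibble(group = names(w), weight = unname(w))
  attr(out, "region") <- region
  out
}

#' France-like synthetic richness weights
#'
#' A fixed, clearly synthetic set of quasi-taxonomic richness weights shaped
#' like a wet-temperate European stream fauna: dominated by Diptera &
#' Hemiptera (true flies alone make up about half of French stream
#' macroinvertebrate species), a modest Hydracarina share, and non-arthropods
#' at 6% of species. Used as the default study condition for the synthetic
#' assemblage generator.
#'
#' @return A [regional_weights()] tibble.
#' @export
default_france_weights <- function() {
  regional_weights(c(
    "Coleoptera & Odonata" = 0.10,
    "Crustaceans" = 0.04,
    "Diptera & Hemiptera" = 0.55,
    "Ephemeroptera" = 0.05,
    "Hydracarina" = 0.12,
    "Non-arthropods" = 0.06,
    "Trichoptera & Plecoptera" = 0.08
  ), region = "synthetic-france-like")
}
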