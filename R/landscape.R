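#' Load a combinatorial variant-activity landscape
#'
#' Reads a tab-separated variant table covering all 32 combinations of the
#' five active-site residues and returns a validated \code{ap_landscape}.
#' The dialect is UTF-8, tab-separated, with \code{#} comment lines and the
#' required header
#' \code{variant  kcat_km  stderr  censor  provenance  km  kcat}.
#' \code{variant} may be a mutation-name (\code{"R166S/E322Y"}) or bitstring
#' form; \code{censor} is one of \code{none}, \code{le} (value is an upper
#' limit) or \code{ge}; \code{provenance} is \code{measured} or
#' \code{calculated}; trailing optional cells may be empty. Two special
#' comment lines, \code{# wt_observed = ...} and \code{# wt_chem_limited =
#' ...}, carry the wild-type reference activities: the observed kcat/KM and
#' the larger value estimated for a rate-limiting chemical step. When absent
#' they default to the WT row's activity.
#'
#' @param path Path to the TSV file.
#' @param wt_convention Which wild-type reference the landscape's WT record
#'   reports by default: \code{"observed"} or \code{"chem_limited"}.
#' @return An \code{ap_landscape}: a data.frame with one row per genotype
#'   (columns \code{genotype}, \code{variant}, \code{kcat_km}, \code{stderr},
#'   \code{censor}, \code{provenance}, \code{km}, \code{kcat}) and attributes
#'   \code{wt_observed}, \code{wt_chem_limited}, \code{wt_convention}.
#' @seealso [builtin_table1()], [write_landscape()], [landscape_activity()]
#' @export
load_landscape <- function(path, wt_convention = c("observed", "chem_limited")) {
  wt_convention <- match.arg(wt_convention)
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  wt_obs <- .comment_value(lines, "wt_observed")
  wt_chem <- .comment_value(lines, "wt_chem_limited")
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  row_no <- which(keep)
  if (length(body) < 1L) stop("empty landscape file", call. = FALSE)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  required <- c("variant", "kcat_km", "stderr", "censor", "provenance", "km", "kcat")
  if (!identical(header[seq_along(required)], required)) {
    stop("malformed header: expected columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  body <- body[-1]
  row_no <- row_no[-1]

  n <- length(body)
  rec <- data.frame(
    genotype = character(n), variant = character(n), kcat_km = NA_real_,
    stderr = NA_real_, censor = character(n), provenance = character(n),
    km = NA_real_, kcat = NA_real_, stringsAsFactors = FALSE
  )
  bad <- character(0)
  num <- function(x) if (is.na(x) || x == "") NA_real_ else suppressWarnings(as.numeric(x))
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    length(f) <- 7L
    f[is.na(f)] <- ""
    g <- tryCatch(parse_variant_name(f[1]), error = function(e) conditionMessage(e))
    v <- num(f[2])
    cens <- if (f[4] == "") "none" else f[4]
    prov <- if (f[5] == "") "measured" else f[5]
    problems <- c(
      if (!grepl("^[01]{5}$", g)) g,
      if (is.na(v) || v <= 0) "kcat_km must be a positive number",
      if (!cens %in% c("none", "le", "ge")) sprintf("bad censor flag '%s'", cens),
      if (!prov %in% c("measured", "calculated")) sprintf("bad provenance '%s'", prov)
    )
    if (length(problems)) {
      bad <- c(bad, sprintf("row %d: %s", row_no[i], paste(problems, collapse = "; ")))
      next
    }
    rec$genotype[i] <- g
    rec$variant[i] <- variant_name(g)
    rec$kcat_km[i] <- v
    rec$stderr[i] <- num(f[3])
    rec$censor[i] <- c(none = "none", le = "upper_limit", ge = "lower_limit")[[cens]]
    rec$provenance[i] <- prov
    rec$km[i] <- num(f[6])
    rec$kcat[i] <- num(f[7])
  }
  if (length(bad)) {
    stop("validation error:\n  ", paste(bad, collapse = "\n  "), call. = FALSE)
  }
  new_landscape(rec, wt_observed = wt_obs, wt_chem_limited = wt_chem,
                wt_convention = wt_convention)
}

.comment_value <- function(lines, key) {
  pat <- paste0("^#\\s*", key, "\\s*=\\s*(\\S+)")
  hit <- grep(pat, lines, value = TRUE)
  if (!length(hit)) return(NA_real_)
  as.numeric(sub(pat, "\\1", hit[1]))
}

#' Construct a validated landscape from a record table
#'
#' Lower-level constructor used by [load_landscape()] and the synthetic
#' generator. Checks completeness over all 32 genotypes, rejects duplicates
#' and non-positive activities.
#'
#' @param records Data.frame with at least \code{genotype} and
#'   \code{kcat_km}; optional \code{stderr}, \code{censor}, \code{provenance},
#'   \code{km}, \code{kcat} are filled with defaults.
#' @param wt_observed,wt_chem_limited Wild-type reference activities
#'   (M^-1 s^-1); default to the WT record's activity.
#' @param wt_convention Default WT reference, \code{"observed"} or
#'   \code{"chem_limited"}.
#' @return An \code{ap_landscape}.
#' @export
new_landscape <- function(records, wt_observed = NA_real_,
                          wt_chem_limited = NA_real_,
                          wt_convention = c("observed", "chem_limited")) {
  wt_convention <- match.arg(wt_convention)
  stopifnot(is.data.frame(records), "genotype" %in% names(records),
            "kcat_km" %in% names(records))
  if (!"variant" %in% names(records)) {
    records$variant <- vapply(records$genotype, variant_name, character(1))
  }
  for (col in c("stderr", "km", "kcat")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  if (!"censor" %in% names(records)) records$censor <- "none"
  if (!"provenance" %in% names(records)) records$provenance <- "measured"

  dup <- records$genotype[duplicated(records$genotype)]
  if (length(dup)) {
    stop("duplicate genotype(s): ",
         paste(unique(vapply(dup, variant_name, character(1))), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(all_genotypes(), records$genotype)
  if (length(missing)) {
    stop("missing genotype(s): ",
         paste(vapply(missing, variant_name, character(1)), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(records$kcat_km) | records$kcat_km <= 0)) {
    stop("all kcat_km values must be positive and finite", call. = FALSE)
  }
  if (any(!is.na(records$stderr) & records$stderr < 0)) {
    stop("stderr must be non-negative", call. = FALSE)
  }
  records <- records[match(all_genotypes(), records$genotype),
                     c("genotype", "variant", "kcat_km", "stderr", "censor",
                       "provenance", "km", "kcat")]
  rownames(records) <- NULL
  wt_row <- records$kcat_km[records$genotype == "11111"]
  if (is.na(wt_observed)) wt_observed <- wt_row
  if (is.na(wt_chem_limited)) wt_chem_limited <- wt_observed
  structure(records,
            wt_observed = wt_observed,
            wt_chem_limited = wt_chem_limited,
            wt_convention = wt_convention,
            class = c("ap_landscape", "data.frame"))
}

#' The packaged Table 1 landscape
#'
#' All 32 variants of the five-residue alkaline phosphatase active-site
#' landscape: 27 measured kcat/KM values plus the wild type, one upper-limit
#' record for the quadruple mutant retaining only D153 (kcat/KM <= 2.0e-2
#' M^-1 s^-1), and four model-derived entries flagged
#' \code{provenance = "calculated"}. The observed WT activity is 3.3e7
#' M^-1 s^-1; the chemistry-limited WT estimate (used as the reference for
#' fold decreases) is 6.3e8 M^-1 s^-1.
#'
#' @inheritParams load_landscape
#' @return An \code{ap_landscape} (see [load_landscape()]).
#' @export
#' @examples
#' ls1 <- builtin_table1()
#' ls1[ls1$variant == "R166S", ]
builtin_table1 <- function(wt_convention = c("observed", "chem_limited")) {
  wt_convention <- match.arg(wt_convention)
  path <- system.file("extdata", "table1.tsv", package = "apsite", mustWork = TRUE)
  load_landscape(path, wt_convention = wt_convention)
}

#' Write a landscape in the canonical TSV dialect
#'
#' Numbers are rendered in two-significant-figure scientific notation
#' (matching the precision of the source kinetic table), so a load/write
#' cycle is idempotent: writing a freshly loaded canonical file reproduces it
#' byte-for-byte.
#'
#' @param landscape An \code{ap_landscape}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "ap_landscape"))
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, format = "e", digits = 1))
  cens <- c(none = "none", upper_limit = "le", lower_limit = "ge")[landscape$censor]
  rows <- paste(landscape$variant, fmt(landscape$kcat_km), fmt(landscape$stderr),
                cens, landscape$provenance, fmt(landscape$km), fmt(landscape$kcat),
                sep = "\t")
  rows <- sub("\t+$", "", rows)  # drop empty trailing optional cells
  header <- c(
    sprintf("# wt_observed = %s", fmt(attr(landscape, "wt_observed"))),
    sprintf("# wt_chem_limited = %s", fmt(attr(landscape, "wt_chem_limited"))),
    paste(c("variant", "kcat_km", "stderr", "censor", "provenance", "km", "kcat"),
          collapse = "\t")
  )
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Look up variant activities with a wild-type reference convention
#'
#' Returns kcat/KM for one or more genotypes. Under the
#' \code{"chem_limited"} convention the WT genotype reports the
#' chemistry-limited reference (the activity expected were the chemical step
#' rate limiting) instead of the smaller observed value; every other genotype
#' is unaffected.
#'
#' @param landscape An \code{ap_landscape}.
#' @param genotype Character vector of bitstrings or variant names.
#' @param wt_convention \code{"observed"} or \code{"chem_limited"}; defaults
#'   to the landscape's own convention.
#' @return Numeric vector of activities (M^-1 s^-1).
#' @export
#' @examples
#' landscape_activity(builtin_table1(), "WT", wt_convention = "chem_limited")
landscape_activity <- function(landscape, genotype, wt_convention = NULL) {
  stopifnot(inherits(landscape, "ap_landscape"))
  if (is.null(wt_convention)) wt_convention <- attr(landscape, "wt_convention")
  wt_convention <- match.arg(wt_convention, c("observed", "chem_limited"))
  g <- vapply(genotype, parse_variant_name, character(1), USE.NAMES = FALSE)
  out <- landscape$kcat_km[match(g, landscape$genotype)]
  if (wt_convention == "chem_limited") {
    out[g == "11111"] <- attr(landscape, "wt_chem_limited")
  }
  out
}

# TRUE where the record is censored (either direction)
.is_censored <- function(landscape, genotype) {
  g <- vapply(genotype, parse_variant_name, character(1), USE.NAMES = FALSE)
  landscape$censor[match(g, landscape$genotype)] != "none"
}

#' @export
print.ap_landscape <- function(x, ...) {
  conv <- attr(x, "wt_convention")
  cat(sprintf(
    "Combinatorial activity landscape: %d genotypes (%d measured, %d calculated, %d censored)\n",
    nrow(x), sum(x$provenance == "measured"), sum(x$provenance == "calculated"),
    sum(x$censor != "none")))
  cat(sprintf("WT reference: observed %.2g, chemistry-limited %.2g M^-1 s^-1 (default: %s)\n\n",
              attr(x, "wt_observed"), attr(x, "wt_chem_limited"), conv))
  print.data.frame(x, digits = 3)
  invisible(x)
}
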