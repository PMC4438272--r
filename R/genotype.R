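#' Canonical active-site residues
#'
#' The five alkaline phosphatase active-site positions analysed by this
#' package, in the canonical order used for bitstring rendering: D101, R166,
#' D153, E322, K328. Absence of E322 is synonymous with absence of the
#' catalytic Mg2+ ion, which requires the E322 carboxylate as a ligand.
#'
#' @return Character vector of the five position labels.
#' @export
#' @examples
#' ap_residues()
ap_residues <- function() c("D101", "R166", "D153", "E322", "K328")

# Mutation aliases denoting *absence* of the wild-type residue. The first
# alias per position is canonical (the mutant set used throughout the study);
# the alternatives were shown to give equivalent effects and map to the same
# absent state.
.ap_aliases <- list(
  D101 = c("D101A", "D101G"),
  R166 = c("R166S", "R166A"),
  D153 = c("D153A", "D153G"),
  E322 = c("E322Y", "E322A"),
  K328 = c("K328A", "K328G")
)

.canonical_alias <- function() vapply(.ap_aliases, `[`, character(1), 1L)

#' Parse a variant name into a genotype bitstring
#'
#' Variant names are either \code{"WT"} or a slash-joined list of mutation
#' aliases (e.g. \code{"R166S/E322Y"}), case- and order-insensitive. A
#' genotype is rendered as a five-character bitstring over the canonical
#' residue order \code{D101, R166, D153, E322, K328}, where \code{1} marks a
#' wild-type residue that is \emph{present}: \code{"11111"} is WT and
#' \code{"00000"} is the minimal enzyme with all five residues removed.
#' Bitstrings themselves are also accepted and returned unchanged.
#'
#' @param name Character scalar: \code{"WT"}, a slash-joined mutation list, or
#'   a five-character bitstring.
#' @return A five-character genotype bitstring.
#' @seealso [variant_name()] for the inverse rendering, [all_genotypes()].
#' @export
#' @examples
#' parse_variant_name("WT")
#' parse_variant_name("R166S/E322Y")
#' parse_variant_name("d101a/r166s/d153a/e322y/k328a")
parse_variant_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, !is.na(name))
  name <- trimws(name)
  if (grepl("^[01]{5}$", name)) return(name)
  if (toupper(name) == "WT") return("11111")
  tokens <- toupper(strsplit(name, "/", fixed = TRUE)[[1]])
  tokens <- trimws(tokens)
  present <- rep(TRUE, 5L)
  names(present) <- ap_residues()
  seen <- character(0)
  for (tok in tokens) {
    hit <- vapply(.ap_aliases, function(a) tok %in% a, logical(1))
    if (!any(hit)) {
      stop(sprintf("unknown mutation alias '%s' in variant name '%s'",
                   tok, name), call. = FALSE)
    }
    pos <- names(.ap_aliases)[hit]
    if (pos %in% seen) {
      stop(sprintf("position %s listed more than once in variant name '%s'",
                   pos, name), call. = FALSE)
    }
    seen <- c(seen, pos)
    present[pos] <- FALSE
  }
  paste(as.integer(present), collapse = "")
}

#' Render a genotype bitstring as a canonical variant name
#'
#' @param genotype Five-character bitstring (see [parse_variant_name()]).
#' @return \code{"WT"} or the slash-joined canonical mutation aliases, in
#'   canonical residue order.
#' @export
#' @examples
#' variant_name("11111")
#' variant_name("10110")
variant_name <- function(genotype) {
  present <- genotype_present(genotype)
  if (all(present)) return("WT")
  paste(.canonical_alias()[!present], collapse = "/")
}

#' @rdname variant_name
#' @return For \code{genotype_present}, a named logical vector over the five
#'   residues indicating which wild-type side chains are present.
#' @export
genotype_present <- function(genotype) {
  stopifnot(is.character(genotype), length(genotype) == 1L,
            grepl("^[01]{5}$", genotype))
  stats::setNames(strsplit(genotype, "")[[1]] == "1", ap_residues())
}

#' Enumerate all genotypes of the residue hypercube
#'
#' @return Character vector of the 32 genotype bitstrings, ordered by the
#'   number of residues present and then lexicographically.
#' @export
#' @examples
#' length(all_genotypes())
all_genotypes <- function() {
  g <- vapply(0:31, function(i) {
    paste(rev(as.integer(intToBits(i)[1:5])), collapse = "")
  }, character(1))
  g[order(nchar(gsub("0", "", g)), g)]
}

# number of residues present
.n_present <- function(genotype) {
  vapply(strsplit(genotype, ""), function(x) sum(x == "1"), integer(1))
}

# set/unset one residue, with domain checks
.genotype_with <- function(genotype, residue, present) {
  idx <- match(residue, ap_residues())
  if (is.na(idx)) stop(sprintf("unknown residue '%s'", residue), call. = FALSE)
  bits <- strsplit(genotype, "")[[1]]
  bits[idx] <- if (present) "1" else "0"
  paste(bits, collapse = "")
}
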