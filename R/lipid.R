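# Lipid shorthand nomenclature: the dialect used in targeted lipidomics
# transition reports. Supported classes are whitelisted; "/" separates
# sn-resolved chains, "_" separates chains at the molecular-species level,
# a single carbon:double-bond token is a sum composition.

.LIPID_CLASSES <- c(
  "Cer", "FAHFA", "HexCer", "LPC O-", "LPC", "LPE O-", "LPE",
  "PA", "PC O-", "PC", "PE O-", "PE", "PG", "PI", "PS", "SM",
  "TG", "DG", "CE")

# expected chain count per class (sum compositions always collapse to 1)
.CHAIN_COUNT <- c(
  Cer = 2L, FAHFA = 2L, HexCer = 2L, `LPC O-` = 1L, LPC = 1L,
  `LPE O-` = 1L, LPE = 1L, PA = 2L, `PC O-` = 2L, PC = 2L,
  `PE O-` = 2L, PE = 2L, PG = 2L, PI = 2L, PS = 2L, SM = 2L,
  TG = 3L, DG = 2L, CE = 1L)

#' Construct a fatty acyl chain descriptor
#'
#' @param carbons integer chain length (>= 2).
#' @param double_bonds integer number of C=C double bonds.
#' @param ether_linkage logical; `TRUE` for an O-/P- ether-linked chain.
#' @param deuterium_count integer count of deuterium labels (e.g. 5 for d5).
#' @return an object of class `fatty_acyl`.
#' @export
fatty_acyl <- function(carbons, double_bonds = 0L, ether_linkage = FALSE,
                       deuterium_count = 0L) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  deuterium_count <- as.integer(deuterium_count)
  if (is.na(carbons) || carbons < 2L)
    stop_snlipid("contract", "fatty acyl needs >= 2 carbons, got %s", carbons)
  if (is.na(double_bonds) || double_bonds < 0L ||
      double_bonds > carbons %/% 2L)
    stop_snlipid("contract", "%d double bonds impossible for %d carbons",
                 double_bonds, carbons)
  if (deuterium_count < 0L)
    stop_snlipid("contract", "negative deuterium count")
  structure(list(carbons = carbons, double_bonds = double_bonds,
                 ether_linkage = isTRUE(ether_linkage),
                 deuterium_count = deuterium_count),
            class = "fatty_acyl")
}

#' @export
format.fatty_acyl <- function(x, ...) format_fatty_acyl(x)

#' Format a fatty acyl as its shorthand token
#'
#' @param fa a [fatty_acyl()].
#' @param with_deuterium append a " d<k>" suffix when labelled.
#' @return character token, e.g. `"18:1"`.
#' @export
format_fatty_acyl <- function(fa, with_deuterium = FALSE) {
  tok <- sprintf("%d:%d", fa$carbons, fa$double_bonds)
  if (with_deuterium && fa$deuterium_count > 0L)
    tok <- sprintf("%s d%d", tok, fa$deuterium_count)
  tok
}

#' @export
print.fatty_acyl <- function(x, ...) {
  cat("<fatty acyl ", format_fatty_acyl(x, with_deuterium = TRUE),
      if (x$ether_linkage) " (ether)", ">\n", sep = "")
  invisible(x)
}

new_lipid_annotation <- function(lipid_class, chains, level, iso_tag = FALSE,
                                 is_istd = FALSE) {
  if (!lipid_class %in% .LIPID_CLASSES)
    stop_snlipid("parse", "unknown lipid class '%s'", lipid_class)
  if (!level %in% c("sum_composition", "molecular_species", "sn_position"))
    stop_snlipid("contract", "unknown annotation level '%s'", level)
  n_expected <- .CHAIN_COUNT[[lipid_class]]
  n <- length(chains)
  if (level == "sum_composition") {
    if (n != 1L)
      stop_snlipid("contract", "sum composition must carry one totals entry")
  } else if (n != n_expected) {
    stop_snlipid("contract", "class %s expects %d chains, got %d",
                 lipid_class, n_expected, n)
  }
  structure(list(lipid_class = lipid_class, chains = chains, level = level,
                 iso_tag = isTRUE(iso_tag), is_istd = isTRUE(is_istd)),
            class = "lipid_annotation")
}

.CHAIN_RE <- "^(O-|P-)?([0-9]+):([0-9]+)$"

.parse_chain <- function(token, deuterium = 0L) {
  m <- regmatches(token, regexec(.CHAIN_RE, token))[[1]]
  if (length(m) == 0L)
    stop_snlipid("parse", "cannot parse chain token '%s'", token)
  fatty_acyl(as.integer(m[3]), as.integer(m[4]),
             ether_linkage = nzchar(m[2]), deuterium_count = deuterium)
}

#' Parse a lipid shorthand name
#'
#' Grammar: `<class>[ ]<chains>[ d<k>][_Iso]` where `<class>` is one of
#' Cer, FAHFA, HexCer, LPC, LPC O-, LPE, LPE O-, PA, PC, PC O-, PE, PE O-,
#' PG, PI, PS, SM, TG, DG, CE and `<chains>` is either a single
#' `carbons:double_bonds` totals token (sum composition), tokens joined by
#' `"_"` (molecular species, chain order not positional) or by `"/"`
#' (sn-resolved: the first chain is sn1). For ether classes the `O-` prefix
#' is part of the class token and marks the first chain
#' (e.g. `"PC O-18:0/20:4"`). A trailing `" d<k>"` attaches `k` deuterium
#' labels to the last chain; a trailing `"_Iso"` marks a compositional-isomer
#' disambiguation tag.
#'
#' @param text a single lipid name string.
#' @param is_istd mark the parsed annotation as an internal standard.
#' @return a `lipid_annotation` (see [fatty_acyl()] for chain fields) with
#'   elements `lipid_class`, `chains`, `level`, `iso_tag`, `is_istd`.
#' @examples
#' parse_lipid("PC 14:0/18:0")   # sn-resolved
#' parse_lipid("PC 18:0_18:2")   # molecular species
#' parse_lipid("PC 36:2")        # sum composition
#' @export
parse_lipid <- function(text, is_istd = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- trimws(text)
  if (!nzchar(raw)) stop_snlipid("parse", "empty lipid name")
  rest <- raw

  iso_tag <- grepl("_Iso$", rest)
  if (iso_tag) rest <- sub("_Iso$", "", rest)

  deut <- 0L
  md <- regmatches(rest, regexec(" d([0-9]+)$", rest))[[1]]
  if (length(md)) {
    deut <- as.integer(md[2])
    rest <- sub(" d[0-9]+$", "", rest)
  }

  # longest class token first so "PC O-" wins over "PC"
  cls <- NA_character_
  for (cand in .LIPID_CLASSES) {
    pref <- if (endsWith(cand, "O-")) cand else paste0(cand, " ")
    if (startsWith(rest, pref)) {
      cls <- cand
      rest <- substring(rest, nchar(pref) + 1L)
      break
    }
  }
  if (is.na(cls))
    stop_snlipid("parse", "no supported lipid class at start of '%s'", raw)
  if (!nzchar(rest))
    stop_snlipid("parse", "lipid name '%s' has no chain tokens", raw)

  if (grepl("/", rest, fixed = TRUE)) {
    level <- "sn_position"; toks <- strsplit(rest, "/", fixed = TRUE)[[1]]
  } else if (grepl("_", rest, fixed = TRUE)) {
    level <- "molecular_species"; toks <- strsplit(rest, "_", fixed = TRUE)[[1]]
  } else {
    level <- "sum_composition"; toks <- rest
  }

  chains <- lapply(seq_along(toks), function(i) {
    .parse_chain(toks[i], deuterium = if (i == length(toks)) deut else 0L)
  })
  if (endsWith(cls, "O-") && !chains[[1]]$ether_linkage)
    chains[[1]]$ether_linkage <- TRUE

  new_lipid_annotation(cls, chains, level, iso_tag = iso_tag,
                       is_istd = is_istd)
}

#' Format a lipid annotation back to its shorthand name
#'
#' Inverse of [parse_lipid()]: `parse_lipid(format_lipid(a))` is identical
#' to `a` for every supported annotation.
#'
#' @param a a `lipid_annotation`.
#' @return the shorthand name string.
#' @export
format_lipid <- function(a) {
  stopifnot(inherits(a, "lipid_annotation"))
  sep <- switch(a$level, sn_position = "/", molecular_species = "_",
                sum_composition = "")
  toks <- vapply(seq_along(a$chains), function(i) {
    fa <- a$chains[[i]]
    tok <- format_fatty_acyl(fa)
    # class-level O- prefix covers the first chain's ether flag
    if (fa$ether_linkage && !(i == 1L && endsWith(a$lipid_class, "O-")))
      tok <- paste0("O-", tok)
    tok
  }, character(1))
  body <- paste(toks, collapse = sep)
  last <- a$chains[[length(a$chains)]]
  if (last$deuterium_count > 0L)
    body <- sprintf("%s d%d", body, last$deuterium_count)
  if (a$iso_tag) body <- paste0(body, "_Iso")
  joiner <- if (endsWith(a$lipid_class, "O-")) "" else " "
  paste0(a$lipid_class, joiner, body)
}

#' @export
format.lipid_annotation <- function(x, ...) format_lipid(x)

#' @export
print.lipid_annotation <- function(x, ...) {
  cat("<lipid ", format_lipid(x), " [", x$level, "]",
      if (x$is_istd) " ISTD", ">\n", sep = "")
  invisible(x)
}

#' The chain-swapped sn-positional counterpart of a diacyl lipid
#'
#' For an sn-resolved two-chain lipid ("SNA" orientation), returns the
#' isomer with the chains exchanged between the sn1 and sn2 positions
#' ("SNB"). Applying the operation twice returns the original annotation.
#'
#' @param a an sn-resolved `lipid_annotation` with exactly two chains.
#' @return the counterpart `lipid_annotation`.
#' @examples
#' format_lipid(sn_counterpart(parse_lipid("PC 14:0/18:0"))) # "PC 18:0/14:0"
#' @export
sn_counterpart <- function(a) {
  stopifnot(inherits(a, "lipid_annotation"))
  if (a$level != "sn_position")
    stop_snlipid("contract", "sn counterpart requires an sn-resolved name, got level '%s'",
                 a$level)
  if (length(a$chains) != 2L)
    stop_snlipid("contract", "sn counterpart requires exactly 2 chains, got %d",
                 length(a$chains))
  b <- a
  b$chains <- rev(a$chains)
  b
}

#' Totals (sum composition) of an annotation
#'
#' @param a a `lipid_annotation`.
#' @return a `fatty_acyl` holding summed carbons and double bonds.
#' @export
sum_composition <- function(a) {
  stopifnot(inherits(a, "lipid_annotation"))
  fatty_acyl(sum(vapply(a$chains, `[[`, integer(1), "carbons")),
             sum(vapply(a$chains, `[[`, integer(1), "double_bonds")),
             ether_linkage = any(vapply(a$chains, `[[`, logical(1),
                                        "ether_linkage")))
}
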