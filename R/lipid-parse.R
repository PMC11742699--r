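#' Parse lipid shorthand species names
#'
#' Decomposes mass-spectrometry shorthand names such as `"PC 32:0"`,
#' `"PE 14:0/14:0"`, `"PC O-34:1"` or `"SM 18:1;O2/18:1[D9]"` into lipid
#' class, total acyl carbons and total carbon-carbon double bonds.
#'
#' Carbons and double bonds are summed over all chain tokens, so chain-level
#' (`"Cer 18:1;O2/14:0"`) and sum-composition (`"Cer 32:1;O2"`) annotations
#' of the same species agree. For sphingolipids the sphingoid-base double
#' bond is part of the chain token and therefore counted; see
#' `vignette("plaquelipids-methods")` for the rationale. Bracketed isotope
#' tags (`[D7]`, `[D9]`, ...) mark labeled internal standards. An `O`
#' directly after the class token (with or without hyphen) marks ether
#' lipids.
#'
#' @param name Character vector of shorthand names.
#' @return A tibble with one row per name: `species_name`, `lipid_class`
#'   (one of PC, `PC O`, PE, PS, PI, SM, Cer, HexCer, LPC, LPE, other),
#'   `total_carbons`, `total_double_bonds`, `is_ether`, `is_lyso`,
#'   `is_labeled_standard`, `hydroxylation` (the `;O`/`;O2` suffix count,
#'   informational).
#' @examples
#' parse_lipid_shorthand(c("PC 32:0", "PE 14:0/14:0", "SM 18:1;O2/18:1[D9]"))
#' @export
parse_lipid_shorthand <- function(name) {
  stopifnot(is.character(name), length(name) > 0)
  rows <- lapply(name, parse_one_shorthand)
  dplyr::bind_rows(rows)
}

known_lipid_classes <- c(
  "HexCer", "LPC", "LPE", "PC", "PE", "PS", "PI", "SM", "Cer"
)

parse_one_shorthand <- function(nm) {
  if (is.na(nm) || !nzchar(trimws(nm))) {
    stop("empty lipid name", call. = FALSE)
  }
  raw <- trimws(nm)
  labeled <- grepl("\\[D[0-9]+\\]", raw)
  x <- gsub("\\[D[0-9]+\\]", "", raw)

  # class token: leading alphabetic word (HexCer first: longest match)
  cls_pat <- paste0("^(", paste(known_lipid_classes, collapse = "|"), ")\\b")
  m <- regmatches(x, regexpr(cls_pat, x))
  if (length(m) == 1) {
    cls <- m
    rest <- trimws(sub(cls_pat, "", x))
  } else {
    generic <- regmatches(x, regexpr("^[A-Za-z][A-Za-z0-9]*", x))
    if (length(generic) == 0) {
      stop("cannot parse lipid name '", nm, "': no class token", call. = FALSE)
    }
    cls <- "other"
    rest <- trimws(sub("^[A-Za-z][A-Za-z0-9]*", "", x))
  }

  is_ether <- FALSE
  if (grepl("^O[- ]", rest) || rest == "O") {
    is_ether <- TRUE
    rest <- trimws(sub("^O[- ]?", "", rest))
  } else if (grepl("^O-", rest)) {
    is_ether <- TRUE
    rest <- trimws(sub("^O-", "", rest))
  }

  chains <- strsplit(rest, "[/_]")[[1]]
  chains <- chains[nzchar(chains)]
  if (length(chains) == 0) {
    stop("cannot parse lipid name '", nm, "': no chain token", call. = FALSE)
  }
  chain_pat <- "^([0-9]+):([0-9]+)(;O([0-9]*))?$"
  carbons <- 0L
  dbs <- 0L
  hydrox <- 0L
  for (ch in chains) {
    ch <- trimws(ch)
    if (!grepl(chain_pat, ch)) {
      stop("cannot parse lipid name '", nm, "': bad chain token '", ch, "'",
        call. = FALSE
      )
    }
    carbons <- carbons + as.integer(sub(chain_pat, "\\1", ch))
    dbs <- dbs + as.integer(sub(chain_pat, "\\2", ch))
    osuf <- sub(chain_pat, "\\4", ch)
    if (grepl(";O", ch)) {
      hydrox <- hydrox + if (nzchar(osuf)) as.integer(osuf) else 1L
    }
  }
  if (carbons <= 0L) {
    stop("cannot parse lipid name '", nm, "': zero carbons", call. = FALSE)
  }

  lipid_class <- if (cls == "PC" && is_ether) "PC O" else cls
  tibble::tibble(
    species_name = nm,
    lipid_class = lipid_class,
    total_carbons = carbons,
    total_double_bonds = dbs,
    is_ether = is_ether,
    is_lyso = cls %in% c("LPC", "LPE"),
    is_labeled_standard = labeled,
    hydroxylation = hydrox
  )
}
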