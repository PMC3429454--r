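#' @keywords internal
"_PACKAGE"

# Canonical lipid class codes, in block order (Cer = block 1 ... TG = block 10;
# PI rides along with the class sums in block 11 because it has too few species
# to form its own block).
LIPID_CLASSES <- c("Cer", "lysoPC", "lysoPE", "PA", "PC", "PE", "PG", "PS",
                   "SM", "TG", "PI")

BLOCK_ORDER <- c(Cer = 1L, lysoPC = 2L, lysoPE = 3L, PA = 4L, PC = 5L,
                 PE = 6L, PG = 7L, PS = 8L, SM = 9L, TG = 10L, PI = 11L)

#' Lipid classes understood by the shorthand parser
#'
#' @return Character vector of canonical class codes.
#' @export
lipid_classes <- function() LIPID_CLASSES

# match a class code case-insensitively against the canonical set
canonical_class <- function(code) {
  hit <- match(tolower(code), tolower(LIPID_CLASSES))
  if (is.na(hit)) {
    stop("unknown lipid class code '", code, "'; allowed codes: ",
         paste(LIPID_CLASSES, collapse = ", "), call. = FALSE)
  }
  LIPID_CLASSES[hit]
}

# parse one chain token like "18:1", "d18:0", "38:7e"
parse_chain_token <- function(token, raw_name) {
  m <- regmatches(token, regexec("^(d?)([0-9]+):([0-9]+)(e?)$", token))[[1]]
  if (length(m) == 0) {
    stop("cannot parse lipid name '", raw_name, "': offending token '",
         token, "'", call. = FALSE)
  }
  list(sphingoid = m[2] == "d",
       carbons = as.integer(m[3]),
       double_bonds = as.integer(m[4]),
       ether = m[5] == "e")
}

# parse one CLASS(...) term into a structured list
parse_term <- function(term, raw_name) {
  m <- regmatches(term, regexec("^([A-Za-z]+)\\((.+)\\)$", term))[[1]]
  if (length(m) == 0) {
    stop("cannot parse lipid name '", raw_name, "': offending token '",
         term, "'", call. = FALSE)
  }
  class_display <- m[2]
  lipid_class <- canonical_class(class_display)
  tokens <- strsplit(m[3], "/", fixed = TRUE)[[1]]
  chains <- lapply(tokens, parse_chain_token, raw_name = raw_name)
  sphingoid_base <- if (chains[[1]]$sphingoid) {
    sprintf("d%d:%d", chains[[1]]$carbons, chains[[1]]$double_bonds)
  } else {
    NA_character_
  }
  if (any(vapply(chains[-1], `[[`, logical(1), "sphingoid"))) {
    stop("cannot parse lipid name '", raw_name,
         "': sphingoid 'd' prefix allowed on the first chain only",
         call. = FALSE)
  }
  list(class_display = class_display,
       lipid_class = lipid_class,
       tokens = chains,
       total_carbons = sum(vapply(chains, `[[`, integer(1), "carbons")),
       total_double_bonds = sum(vapply(chains, `[[`, integer(1), "double_bonds")),
       ether = any(vapply(chains, `[[`, logical(1), "ether")),
       sphingoid_base = sphingoid_base,
       resolved = length(chains) > 1L)
}

# split a composite name "PC(37:4)/PE(40:4)" or "PE(38:4)+PC(35:4)" into
# top-level CLASS(...) terms; separators inside parentheses do not count
split_terms <- function(raw_name) {
  chars <- strsplit(raw_name, "")[[1]]
  depth <- 0L
  cut <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (depth == 0L && chars[i] %in% c("+", "/")) cut <- c(cut, i)
  }
  if (depth != 0L) {
    stop("cannot parse lipid name '", raw_name, "': unbalanced parentheses",
         call. = FALSE)
  }
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  terms <- mapply(function(s, e) substr(raw_name, s, e), starts, ends)
  seps <- chars[cut]
  if (any(!nzchar(terms))) {
    stop("cannot parse lipid name '", raw_name, "': empty term", call. = FALSE)
  }
  list(terms = terms, separators = seps)
}

#' Parse a shorthand lipid name
#'
#' Parses sum-composition shorthand such as `"TG(58:10)"`, chain-resolved
#' names such as `"SM(d18:0/24:0)"`, ether species (`"PE(38:7e)"`), and
#' ambiguous double assignments joined by `+` or `/` such as
#' `"PC(37:4)/PE(40:4)"`, in which case the first-listed term is the primary
#' identity and the alternatives are retained in `ambiguous_with`.
#'
#' @param raw_name Shorthand name, e.g. `"PC(38:4)"`.
#' @param peak_id Unique peak identifier; names may repeat across distinct
#'   peaks, so identity is always the peak id, never the name.
#' @param identified Logical, whether the peak has a confirmed identity.
#' @return An object of class `lipid_species`: a list with fields `peak_id`,
#'   `raw_name`, `lipid_class`, `total_carbons`, `total_double_bonds`,
#'   `ether`, `sphingoid_base`, `chains` (list of `c(carbons, double_bonds)`
#'   or `NULL` when only the sum composition is known), `ambiguous_with`
#'   (list of alternative parses) and `identified`.
#' @examples
#' parse_lipid_name("SM(d18:0/24:0)")
#' parse_lipid_name("PC(37:4)/PE(40:4)")
#' @export
parse_lipid_name <- function(raw_name, peak_id = raw_name, identified = TRUE) {
  stopifnot(is.character(raw_name), length(raw_name) == 1L, nzchar(raw_name))
  parts <- split_terms(raw_name)
  terms <- lapply(parts$terms, parse_term, raw_name = raw_name)
  primary <- terms[[1]]
  chains <- NULL
  if (primary$resolved) {
    chains <- lapply(primary$tokens, function(ch) {
      c(carbons = ch$carbons, double_bonds = ch$double_bonds)
    })
  }
  ambiguous_with <- lapply(terms[-1], function(tm) {
    list(lipid_class = tm$lipid_class,
         total_carbons = tm$total_carbons,
         total_double_bonds = tm$total_double_bonds)
  })
  structure(list(peak_id = peak_id,
                 raw_name = raw_name,
                 lipid_class = primary$lipid_class,
                 total_carbons = primary$total_carbons,
                 total_double_bonds = primary$total_double_bonds,
                 ether = primary$ether,
                 sphingoid_base = primary$sphingoid_base,
                 chains = chains,
                 ambiguous_with = ambiguous_with,
                 identified = isTRUE(identified),
                 terms = terms,
                 separators = parts$separators),
            class = "lipid_species")
}

render_term <- function(tm) {
  body <- vapply(tm$tokens, function(ch) {
    sprintf("%s%d:%d%s", if (ch$sphingoid) "d" else "",
            ch$carbons, ch$double_bonds, if (ch$ether) "e" else "")
  }, character(1))
  sprintf("%s(%s)", tm$class_display, paste(body, collapse = "/"))
}

#' Re-render a parsed lipid name
#'
#' Rebuilds the shorthand string from the parsed structure; for any name the
#' parser accepts, `format(parse_lipid_name(x)) == x`.
#'
#' @param x A `lipid_species` object.
#' @param ... Unused.
#' @export
format.lipid_species <- function(x, ...) {
  rendered <- vapply(x$terms, render_term, character(1))
  out <- rendered[1]
  if (length(rendered) > 1L) {
    for (i in seq_along(x$separators)) {
      out <- paste0(out, x$separators[i], rendered[i + 1L])
    }
  }
  out
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s [%s] C%d:%d%s%s\n", x$raw_name,
              x$lipid_class, x$total_carbons, x$total_double_bonds,
              if (x$ether) " ether" else "",
              if (!is.na(x$sphingoid_base)) paste0(" ", x$sphingoid_base) else ""))
  if (length(x$ambiguous_with)) {
    alts <- vapply(x$ambiguous_with, function(a) {
      sprintf("%s %d:%d", a$lipid_class, a$total_carbons, a$total_double_bonds)
    }, character(1))
    cat("  ambiguous with:", paste(alts, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Parse a species annotation table
#'
#' @param annotations A data frame with columns `peak_id`, `raw_name` and
#'   optionally `identified` (default `TRUE`).
#' @return A data frame with one row per peak: `peak_id`, `raw_name`,
#'   `lipid_class`, `total_carbons`, `total_double_bonds`, `ether`,
#'   `sphingoid_base`, `identified`, `block`, plus list columns `chains` and
#'   `ambiguous_with`.
#' @export
annotate_species <- function(annotations) {
  stopifnot(is.data.frame(annotations),
            all(c("peak_id", "raw_name") %in% names(annotations)))
  if (anyDuplicated(annotations$peak_id)) {
    stop("peak_id must be unique (raw names may repeat, peak ids may not)")
  }
  identified <- if ("identified" %in% names(annotations)) {
    as.logical(annotations$identified)
  } else {
    rep(TRUE, nrow(annotations))
  }
  parsed <- mapply(parse_lipid_name, annotations$raw_name,
                   annotations$peak_id, identified,
                   SIMPLIFY = FALSE, USE.NAMES = FALSE)
  out <- data.frame(
    peak_id = vapply(parsed, `[[`, character(1), "peak_id"),
    raw_name = vapply(parsed, `[[`, character(1), "raw_name"),
    lipid_class = vapply(parsed, `[[`, character(1), "lipid_class"),
    total_carbons = vapply(parsed, `[[`, integer(1), "total_carbons"),
    total_double_bonds = vapply(parsed, `[[`, integer(1), "total_double_bonds"),
    ether = vapply(parsed, `[[`, logical(1), "ether"),
    sphingoid_base = vapply(parsed, `[[`, character(1), "sphingoid_base"),
    identified = vapply(parsed, `[[`, logical(1), "identified"),
    stringsAsFactors = FALSE
  )
  out$block <- block_index(out$lipid_class)
  out$chains <- lapply(parsed, `[[`, "chains")
  out$ambiguous_with <- lapply(parsed, `[[`, "ambiguous_with")
  out
}

#' Internal standard assigned to a lipid class
#'
#' Each lipid class is quantified against one spiked internal standard:
#' monoacyl glycerophospholipids (lysoPC, lysoPE) against PC(17:0/0:0),
#' diacyl glycerophospholipids other than ethanolamine lipids (PC, PA, PG,
#' PI, PS) against PC(17:0/17:0), diacyl PE against PE(17:0/17:0), ceramides
#' against Cer(d18:1/17:0), and triglycerides (with cholesteryl esters, were
#' any present) against TG(17:0/17:0/17:0). The sphingomyelin assignment is
#' not fixed by the normalization convention above and is therefore an
#' explicit argument.
#'
#' @param lipid_class Character vector of canonical class codes.
#' @param sm_standard Standard used for SM species.
#' @param overrides Optional named character vector mapping class codes to
#'   standard names, taking precedence over the built-in map.
#' @return Character vector of standard names, same length as `lipid_class`.
#' @export
standard_for_class <- function(lipid_class,
                               sm_standard = "PC(17:0/17:0)",
                               overrides = NULL) {
  map <- c(lysoPC = "PC(17:0/0:0)",
           lysoPE = "PC(17:0/0:0)",
           PC = "PC(17:0/17:0)",
           PA = "PC(17:0/17:0)",
           PG = "PC(17:0/17:0)",
           PI = "PC(17:0/17:0)",
           PS = "PC(17:0/17:0)",
           Cer = "Cer(d18:1/17:0)",
           PE = "PE(17:0/17:0)",
           TG = "TG(17:0/17:0/17:0)",
           SM = sm_standard)
  if (!is.null(overrides)) map[names(overrides)] <- overrides
  bad <- setdiff(unique(lipid_class), names(map))
  if (length(bad)) {
    stop("no internal standard mapped for class(es): ",
         paste(bad, collapse = ", "),
         "; provide them via 'overrides'", call. = FALSE)
  }
  unname(map[lipid_class])
}

#' Block number of a lipid class in the multi-block layout
#'
#' The 11-block layout orders the class blocks Cer, lysoPC, lysoPE, PA, PC,
#' PE, PG, PS, SM, TG (blocks 1-10); block 11 holds the per-class totals
#' ("sums of lipids") together with the PI species, which are too few to form
#' a block of their own.
#'
#' @param lipid_class Character vector of canonical class codes.
#' @return Integer vector of block numbers in 1..11.
#' @export
block_index <- function(lipid_class) {
  bad <- setdiff(unique(lipid_class), names(BLOCK_ORDER))
  if (length(bad)) {
    stop("unknown lipid class code(s): ", paste(bad, collapse = ", "),
         "; allowed codes: ", paste(LIPID_CLASSES, collapse = ", "),
         call. = FALSE)
  }
  unname(BLOCK_ORDER[lipid_class])
}
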