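#' Read a reaction-network model from the plain-text model DSL
#'
#' The DSL is line-oriented. Blank lines and `#` comments are ignored.
#' Species lines are `species <name> <initial> [tag]`. Reaction lines are
#' `reaction <id>: <reactants> -> <products> <kf>` for irreversible and
#' `reaction <id>: <reactants> <-> <products> <kf> <kr>` for reversible
#' reactions, where each side is a `+`-separated list of `[coef] species`
#' terms (e.g. `2 A + B`) or `0` for an empty side.
#'
#' @param path Path to a DSL file (or a character vector of lines via
#'   `text`).
#' @param text Optional character vector of DSL lines, used instead of
#'   `path`.
#' @return A [reaction_network()].
#' @seealso [write_model_dsl()] for the inverse operation.
#' @export
read_model_dsl <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  species <- list()
  reactions <- list()
  parse_side <- function(s, id) {
    s <- trimws(s)
    if (s == "0" || s == "") return(stats::setNames(integer(0), character(0)))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- integer(0)
    for (term in terms) {
      tok <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(tok) == 1L) {
        coef <- 1L; name <- tok
      } else if (length(tok) == 2L && grepl("^[0-9]+$", tok[1])) {
        coef <- as.integer(tok[1]); name <- tok[2]
      } else {
        stop("reaction '", id, "': cannot parse term '", term, "'")
      }
      out[name] <- (if (name %in% names(out)) out[[name]] else 0L) + coef
    }
    out
  }
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "species") {
      if (length(tok) < 3L) stop("malformed species line: '", ln, "'")
      species[[length(species) + 1L]] <- species_def(
        tok[2], as.numeric(tok[3]),
        if (length(tok) >= 4L) tok[4] else NA_character_)
    } else if (tok[1] == "reaction") {
      m <- regmatches(ln, regexec(
        "^reaction[[:space:]]+([^:[:space:]]+):(.*)$", ln))[[1]]
      if (length(m) != 3L) stop("malformed reaction line: '", ln, "'")
      id <- m[2]; body <- m[3]
      reversible <- grepl("<->", body, fixed = TRUE)
      arrow <- if (reversible) "<->" else "->"
      halves <- strsplit(body, arrow, fixed = TRUE)[[1]]
      if (length(halves) != 2L) stop("malformed reaction line: '", ln, "'")
      lhs <- halves[1]
      rhs_tok <- strsplit(trimws(halves[2]), "[[:space:]]+")[[1]]
      n_par <- if (reversible) 2L else 1L
      if (length(rhs_tok) < n_par + 1L) {
        stop("reaction '", id, "': missing rate parameter(s)")
      }
      pars <- utils::tail(rhs_tok, n_par)
      prod_str <- paste(utils::head(rhs_tok, length(rhs_tok) - n_par),
                        collapse = " ")
      reactions[[length(reactions) + 1L]] <- reaction(
        id,
        reactants = parse_side(lhs, id),
        products = parse_side(prod_str, id),
        kf = pars[1],
        kr = if (reversible) pars[2] else NULL)
    } else {
      stop("unrecognized DSL line: '", ln, "'")
    }
  }
  reaction_network(species, reactions)
}

#' Write a reaction network to the model DSL
#'
#' @param net A [reaction_network()].
#' @param path Output file path; if `NULL` the DSL lines are returned
#'   invisibly without writing.
#' @return The character vector of DSL lines, invisibly.
#' @export
write_model_dsl <- function(net, path = NULL) {
  stopifnot(is.reaction_network(net))
  fmt_side <- function(stoich) {
    if (length(stoich) == 0L) return("0")
    paste(ifelse(stoich == 1L, names(stoich),
                 paste(stoich, names(stoich))), collapse = " + ")
  }
  sp_lines <- vapply(seq_len(nrow(net$species)), function(i) {
    tag <- net$species$tag[i]
    paste(c("species", net$species$name[i],
            format(net$species$initial[i], scientific = FALSE),
            if (!is.na(tag)) tag), collapse = " ")
  }, character(1))
  rx_lines <- vapply(net$reactions, function(r) {
    arrow <- if (r$reversible) "<->" else "->"
    paste(c(sprintf("reaction %s: %s %s %s", r$id, fmt_side(r$reactants),
                    arrow, fmt_side(r$products)), r$kf, r$kr), collapse = " ")
  }, character(1))
  lines <- c(sp_lines, unname(rx_lines))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Import a mass-action SBML model
#'
#' Minimal SBML Level 3 importer restricted to mass-action kinetic laws:
#' every kinetic law must be a product `k * S1 * S2 * ...` of one parameter
#' and the reaction's reactant species (reverse part `- kr * P1 * ...` for
#' reversible reactions). Any other rate law is rejected.
#'
#' @param path Path to an SBML file.
#' @return A [reaction_network()].
#' @export
read_sbml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("the xml2 package is required for SBML import")
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  species <- lapply(sp_nodes, function(n) {
    species_def(xml2::xml_attr(n, "id"),
                as.numeric(xml2::xml_attr(n, "initialAmount")))
  })
  monomial_of <- function(apply_node, ctx) {
    ## expects <apply><times/><ci>k</ci><ci>x</ci>...</apply> or a lone <ci>
    kids <- xml2::xml_find_all(apply_node, "./*")
    if (xml2::xml_name(kids[[1]]) != "times") {
      stop("non-mass-action kinetic law in reaction '", ctx,
           "': expected a product of a rate constant and species")
    }
    vapply(kids[-1], function(k) {
      if (xml2::xml_name(k) != "ci") {
        stop("non-mass-action kinetic law in reaction '", ctx, "'")
      }
      trimws(xml2::xml_text(k))
    }, character(1))
  }
  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(n) {
    id <- xml2::xml_attr(n, "id")
    reversible <- identical(xml2::xml_attr(n, "reversible"), "true")
    side <- function(xp) {
      refs <- xml2::xml_find_all(n, xp)
      st <- vapply(refs, function(r) {
        s <- xml2::xml_attr(r, "stoichiometry")
        if (is.na(s)) 1L else as.integer(as.numeric(s))
      }, integer(1))
      stats::setNames(st, vapply(refs, xml2::xml_attr, character(1),
                                 "species"))
    }
    reactants <- side("./listOfReactants/speciesReference")
    products <- side("./listOfProducts/speciesReference")
    math <- xml2::xml_find_first(n, "./kineticLaw/math/apply")
    if (inherits(math, "xml_missing")) {
      stop("reaction '", id, "' has no kinetic law")
    }
    op <- xml2::xml_name(xml2::xml_find_first(math, "./*"))
    check_terms <- function(terms, stoich, what) {
      expected <- rep(names(stoich), times = stoich)
      if (!setequal(terms[-1], unique(expected)) ||
          !identical(sort(terms[-1]), sort(expected))) {
        stop("non-mass-action kinetic law in reaction '", id,
             "': ", what, " monomial does not match stoichiometry")
      }
      terms[1]
    }
    if (op == "minus") {
      if (!reversible) {
        stop("reaction '", id,
             "' has a two-term rate law but is not marked reversible")
      }
      parts <- xml2::xml_find_all(math, "./apply")
      if (length(parts) != 2L) {
        stop("non-mass-action kinetic law in reaction '", id, "'")
      }
      kf <- check_terms(monomial_of(parts[[1]], id), reactants, "forward")
      kr <- check_terms(monomial_of(parts[[2]], id), products, "reverse")
      reaction(id, reactants, products, kf = kf, kr = kr)
    } else if (op == "times") {
      if (reversible) {
        stop("reversible reaction '", id,
             "' must have a forward-minus-reverse mass-action law")
      }
      kf <- check_terms(monomial_of(math, id), reactants, "forward")
      reaction(id, reactants, products, kf = kf)
    } else {
      stop("non-mass-action kinetic law in reaction '", id,
           "' (operator '", op, "')")
    }
  })
  reaction_network(species, reactions)
}
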