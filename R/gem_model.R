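# Genome-scale metabolic model container and I/O.
#
# Flux convention: exchange reactions are written "metabolite -> (nothing)",
# so uptake is a negative flux.  All bounds are in model flux units
# (mmol/gCDW normalized by the fixed growth value of the scoring
# configuration).

REACTION_CATEGORIES <- c("internal", "exchange", "transport", "diffusion",
                         "biomass")

#' Construct a metabolic network
#'
#' The central container: a metabolites-by-reactions stoichiometric matrix
#' with per-reaction flux bounds, gene-annotation flags, category tags and a
#' designated growth (biomass) reaction.
#'
#' @param stoich metabolites x reactions matrix (dense or sparse) with row
#'   and column names giving metabolite and reaction ids.
#' @param lb,ub per-reaction flux bounds.
#' @param growth_reaction id of the biomass/growth reaction.
#' @param gene_associated logical per reaction; defaults to `TRUE` for
#'   internal reactions and `FALSE` for pseudo-reactions (exchange, biomass).
#' @param category per-reaction tag in
#'   `c("internal","exchange","transport","diffusion","biomass")`; entries
#'   given as `NA` (or omitted) are auto-tagged: single-nonzero columns as
#'   `exchange`, pure cross-compartment carriers as `transport`, the growth
#'   reaction as `biomass`, the rest as `internal`.
#' @param product_exchange optional id of the heterologous product's exchange
#'   reaction.
#' @param met_base optional metabolite base names (compartment stripped),
#'   used for transport detection; defaults to ids with a trailing
#'   `[compartment]` suffix removed.
#' @return an object of class `metabolic_network`.
#' @export
metabolic_network <- function(stoich, lb, ub, growth_reaction,
                              gene_associated = NULL, category = NULL,
                              product_exchange = NULL, met_base = NULL) {
  S <- methods::as(methods::as(Matrix::Matrix(stoich, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  mets <- rownames(S)
  rxns <- colnames(S)
  if (is.null(mets) || is.null(rxns)) {
    stop("stoich must carry metabolite row names and reaction column names")
  }
  if (anyDuplicated(rxns)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxns[duplicated(rxns)]), collapse = ", "))
  }
  if (anyDuplicated(mets)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets[duplicated(mets)]), collapse = ", "))
  }
  n <- length(rxns)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub)) stop("lower bound exceeds upper bound for: ",
                         paste(rxns[lb > ub], collapse = ", "))
  if (!growth_reaction %in% rxns) {
    stop("growth reaction '", growth_reaction, "' not in model")
  }
  if (!is.null(product_exchange) && !product_exchange %in% rxns) {
    stop("product exchange '", product_exchange, "' not in model")
  }
  if (is.null(met_base)) met_base <- sub("\\[[^][]*\\]$", "", mets)
  if (is.null(category)) category <- rep(NA_character_, n)
  category <- as.character(category)
  category[!is.na(category) & category == "auto"] <- NA_character_
  bad <- !is.na(category) & !category %in% REACTION_CATEGORIES
  if (any(bad)) stop("unknown category: ", paste(unique(category[bad]),
                                                 collapse = ", "))
  category <- autotag_categories(S, rxns, met_base, growth_reaction, category)
  if (is.null(gene_associated)) {
    gene_associated <- category == "internal"
  }
  model <- structure(
    list(mets = mets, rxns = rxns, S = S,
         lb = as.numeric(lb), ub = as.numeric(ub),
         gene_associated = as.logical(gene_associated),
         category = category, growth_reaction = growth_reaction,
         product_exchange = product_exchange, met_base = met_base,
         knockouts = character(0), environment = character(0)),
    class = "metabolic_network")
  validate_network(model)
  model
}

autotag_categories <- function(S, rxns, met_base, growth_reaction, category) {
  nnz_per_col <- diff(S@p)
  for (j in seq_along(rxns)) {
    if (!is.na(category[j])) next
    if (rxns[j] == growth_reaction) {
      category[j] <- "biomass"
    } else if (nnz_per_col[j] == 1L) {
      category[j] <- "exchange"
    } else {
      idx <- (S@p[j] + 1L):S@p[j + 1L]
      rows <- S@i[idx] + 1L
      vals <- S@x[idx]
      net <- tapply(vals, met_base[rows], sum)
      same_species <- all(abs(net) < 1e-12) &&
        length(unique(met_base[rows])) < length(rows)
      category[j] <- if (same_species) "transport" else "internal"
    }
  }
  category
}

#' Validate metabolic-network invariants
#'
#' Checks id uniqueness, bound ordering, matrix dimensions, the designated
#' growth reaction, and that every exchange-tagged reaction has exactly one
#' nonzero stoichiometric entry.  Called by the constructor and again after
#' any augmentation.
#'
#' @param model a `metabolic_network`.
#' @return the model, invisibly; errors on violation.
#' @export
validate_network <- function(model) {
  stopifnot(inherits(model, "metabolic_network"))
  S <- model$S
  if (nrow(S) != length(model$mets) || ncol(S) != length(model$rxns)) {
    stop("stoichiometric matrix dimensions disagree with id lists")
  }
  if (anyDuplicated(model$rxns) || anyDuplicated(model$mets)) {
    stop("duplicate ids")
  }
  if (any(model$lb > model$ub)) stop("lb > ub")
  if (sum(model$rxns == model$growth_reaction) != 1L) {
    stop("exactly one growth reaction required")
  }
  nnz <- diff(S@p)
  bad_ex <- model$category == "exchange" & nnz != 1L
  if (any(bad_ex)) {
    stop("exchange reactions with more than one metabolite: ",
         paste(model$rxns[bad_ex], collapse = ", "))
  }
  invisible(model)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic_network:", length(x$mets), "metabolites,",
      length(x$rxns), "reactions\n")
  cat("  growth reaction:", x$growth_reaction, "\n")
  if (!is.null(x$product_exchange)) {
    cat("  product exchange:", x$product_exchange, "\n")
  }
  tab <- table(x$category)
  cat("  categories:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  if (length(x$knockouts)) {
    cat("  view knockouts:", paste(x$knockouts, collapse = ", "), "\n")
  }
  if (length(x$environment)) {
    cat("  view environment:", paste(x$environment, collapse = ", "), "\n")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# reaction equation strings ("A + 2 B -> C"; "<->" marks reversible intent,
# bounds are authoritative; an empty side denotes the environment)

parse_reaction_equation <- function(eq) {
  arrow <- if (grepl("<->", eq, fixed = TRUE)) "<->" else
    if (grepl("->", eq, fixed = TRUE)) "->" else
      stop("no '->' or '<->' arrow in equation: ", eq)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L) stop("malformed equation: ", eq)
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (s == "") return(numeric(0))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    coeffs <- numeric(0)
    for (term in terms) {
      if (term == "") stop("empty term in equation: ", eq)
      mm <- regmatches(term,
                       regexec("^([0-9]*\\.?[0-9]+)\\s+(.+)$", term))[[1]]
      if (length(mm) == 3L) {
        coeffs[mm[3]] <- sign * as.numeric(mm[2])
      } else {
        coeffs[term] <- sign * 1
      }
    }
    coeffs
  }
  left <- parse_side(sides[1], -1)
  right <- parse_side(sides[2], +1)
  out <- left
  for (m in names(right)) out[m] <- (if (m %in% names(out)) out[m] else 0) +
      right[m]
  out[out != 0]
}

format_reaction_equation <- function(coeffs) {
  fmt_side <- function(v) {
    if (length(v) == 0L) return("")
    paste(ifelse(abs(v) == 1, names(v),
                 paste(format(abs(v), trim = TRUE, scientific = FALSE),
                       names(v))),
          collapse = " + ")
  }
  left <- coeffs[coeffs < 0]
  right <- coeffs[coeffs > 0]
  trimws(paste(fmt_side(left), "->", fmt_side(right)))
}

# ---------------------------------------------------------------------------
# tabular toy-model format: TSV with columns
#   id  equation  lb  ub  category  [gene_associated]

#' Read a tabular toy model
#'
#' One reaction per line: `id`, a human-readable equation string
#' (`"A + 2 B -> C"`), `lb`, `ub`, `category` (or `auto`), and optionally a
#' 0/1 `gene_associated` column.
#'
#' @param path TSV file path.
#' @param growth_reaction explicit growth-reaction id; when `NULL` the first
#'   reaction whose category is `biomass`, or whose id matches
#'   `biomass|growth` (case-insensitively), is used.
#' @param product_exchange optional product exchange id.
#' @return a `metabolic_network`.
#' @export
read_toy_model <- function(path, growth_reaction = NULL,
                           product_exchange = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  req <- c("id", "equation", "lb", "ub")
  if (!all(req %in% names(tab))) {
    stop("toy model file must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate reaction ids in ", path, ": ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  coeff_list <- lapply(tab$equation, parse_reaction_equation)
  mets <- unique(unlist(lapply(coeff_list, names)))
  S <- matrix(0, length(mets), nrow(tab), dimnames = list(mets, tab$id))
  for (j in seq_along(coeff_list)) {
    S[names(coeff_list[[j]]), j] <- coeff_list[[j]]
  }
  category <- if ("category" %in% names(tab)) tab$category else
    rep(NA_character_, nrow(tab))
  if (is.null(growth_reaction)) {
    growth_reaction <- identify_growth_reaction(tab$id, category)
  }
  gene <- if ("gene_associated" %in% names(tab)) {
    as.logical(as.integer(tab$gene_associated))
  } else NULL
  metabolic_network(S, tab$lb, tab$ub, growth_reaction,
                    gene_associated = gene, category = category,
                    product_exchange = product_exchange)
}

identify_growth_reaction <- function(ids, category) {
  hit <- which(!is.na(category) & category == "biomass")
  if (length(hit) == 0L) hit <- grep("biomass|growth", ids,
                                     ignore.case = TRUE)
  if (length(hit) == 0L) stop("no identifiable growth reaction")
  ids[hit[1]]
}

#' Write a model in the tabular toy format
#'
#' @param model a `metabolic_network`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_toy_model <- function(model, path) {
  eqs <- vapply(seq_along(model$rxns), function(j) {
    col <- model$S[, j]
    format_reaction_equation(col[col != 0])
  }, character(1))
  tab <- data.frame(id = model$rxns, equation = eqs, lb = model$lb,
                    ub = model$ub, category = model$category,
                    gene_associated = as.integer(model$gene_associated))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SBML Level 3 + fbc reader (species, reactions, flux bounds via parameters,
# active fbc objective, gene-product associations)

#' Read an SBML Level 3 (fbc) model
#'
#' Minimal reader for constraint-based models: species, reactions with
#' stoichiometry, flux bounds resolved through `fbc:lowerFluxBound` /
#' `fbc:upperFluxBound` parameters (falling back to the `reversible` flag),
#' the active flux objective, and the presence of gene-product associations.
#'
#' @inheritParams read_toy_model
#' @return a `metabolic_network`.
#' @export
read_sbml_model <- function(path, growth_reaction = NULL,
                            product_exchange = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- xml2::read_xml(path)
  ns <- c(s = xml2::xml_ns(doc)[["d1"]])

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(species, "id")
  sp_comp <- xml2::xml_attr(species, "compartment")
  sp_boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  keep <- !sp_boundary
  mets <- sp_id[keep]
  comp <- sp_comp[keep]
  met_base <- mets
  has_comp <- !is.na(comp) & comp != "" &
    mapply(function(m, cc) endsWith(m, paste0("_", cc)), mets, comp)
  met_base[has_comp] <- substr(mets[has_comp], 1,
                               nchar(mets[has_comp]) -
                                 nchar(comp[has_comp]) - 1L)

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx_nodes) == 0L) stop("no reactions found in ", path)
  rxns <- xml2::xml_attr(rx_nodes, "id")
  if (anyDuplicated(rxns)) stop("duplicate reaction ids in SBML")
  n <- length(rxns)
  lb <- numeric(n); ub <- numeric(n); gene <- logical(n)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  met_index <- stats::setNames(seq_along(mets), mets)
  for (j in seq_len(n)) {
    node <- rx_nodes[[j]]
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node,
                                 paste0("./s:", side, "/s:speciesReference"),
                                 ns)
      if (length(refs) == 0L) next
      sp <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      if (side == "listOfReactants") st <- -st
      in_model <- sp %in% mets
      trip_i <- c(trip_i, met_index[sp[in_model]])
      trip_j <- c(trip_j, rep(j, sum(in_model)))
      trip_x <- c(trip_x, st[in_model])
    }
    lbp <- xml2::xml_attr(node, "lowerFluxBound")
    ubp <- xml2::xml_attr(node, "upperFluxBound")
    rev <- xml2::xml_attr(node, "reversible") %in% "true"
    lb[j] <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else
      if (rev) -Inf else 0
    ub[j] <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else Inf
    gpa <- xml2::xml_find_first(node, ".//*[local-name()='geneProductAssociation']")
    gene[j] <- !inherits(gpa, "xml_missing")
  }
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(length(mets), n),
                            dimnames = list(mets, rxns))
  # duplicate species references within a reaction are summed by
  # sparseMatrix; that matches SBML semantics

  if (is.null(growth_reaction)) {
    obj <- xml2::xml_find_first(
      doc, ".//*[local-name()='listOfObjectives']//*[local-name()='fluxObjective']")
    if (!inherits(obj, "xml_missing")) {
      growth_reaction <- xml2::xml_attr(obj, "reaction")
    }
    if (is.null(growth_reaction) || is.na(growth_reaction)) {
      growth_reaction <- identify_growth_reaction(rxns,
                                                  rep(NA_character_, n))
    }
  }
  metabolic_network(S, lb, ub, growth_reaction, gene_associated = gene,
                    product_exchange = product_exchange,
                    met_base = met_base)
}

#' Load a metabolic model from SBML or the tabular toy format
#'
#' Dispatches on file extension: `.xml`/`.sbml` to the SBML reader,
#' everything else to the tabular reader.
#'
#' @inheritParams read_toy_model
#' @return a `metabolic_network`.
#' @export
load_model <- function(path, growth_reaction = NULL,
                       product_exchange = NULL) {
  if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
    read_sbml_model(path, growth_reaction, product_exchange)
  } else {
    read_toy_model(path, growth_reaction, product_exchange)
  }
}

# ---------------------------------------------------------------------------
# pathway augmentation

#' Define a heterologous pathway
#'
#' @param reactions a list, one element per reaction, each a list with
#'   `id`, `coeffs` (named numeric, metabolite -> coefficient), `lb`, `ub`,
#'   and optionally `category`.
#' @param new_metabolites metabolite ids introduced by the pathway; any
#'   metabolite in `coeffs` not present in the host model must be listed
#'   here.
#' @return an object of class `pathway_definition`.
#' @export
pathway_definition <- function(reactions, new_metabolites = character(0)) {
  for (r in reactions) {
    stopifnot(is.character(r$id), is.numeric(r$coeffs),
              !is.null(names(r$coeffs)), r$lb <= r$ub)
  }
  structure(list(reactions = reactions,
                 new_metabolites = new_metabolites),
            class = "pathway_definition")
}

#' Read a pathway definition from TSV
#'
#' Columns: `reaction_id`, `equation`, `lb`, `ub`.  Metabolites that do not
#' occur in the host model are treated as new.
#'
#' @param path TSV file path.
#' @return a `pathway_definition` (with `new_metabolites` filled in at
#'   [add_pathway()] time).
#' @export
read_pathway_tsv <- function(path) {
  if (!file.exists(path)) stop("pathway file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  req <- c("reaction_id", "equation", "lb", "ub")
  if (!all(req %in% names(tab))) {
    stop("pathway file must have columns: ", paste(req, collapse = ", "))
  }
  reactions <- lapply(seq_len(nrow(tab)), function(i) {
    list(id = tab$reaction_id[i],
         coeffs = parse_reaction_equation(tab$equation[i]),
         lb = tab$lb[i], ub = tab$ub[i])
  })
  all_mets <- unique(unlist(lapply(reactions, function(r) names(r$coeffs))))
  pathway_definition(reactions, new_metabolites = all_mets)
}

#' Add a heterologous pathway to a model
#'
#' Appends the pathway's reactions (and any new metabolites) as new columns
#' of the stoichiometric matrix.  The host model is not modified.  The last
#' pathway reaction tagged `exchange` (typically the product drain) becomes
#' the model's `product_exchange` unless one is already set.
#'
#' @param model a `metabolic_network`.
#' @param pathway a `pathway_definition`.
#' @return the augmented `metabolic_network`.
#' @export
add_pathway <- function(model, pathway) {
  stopifnot(inherits(model, "metabolic_network"),
            inherits(pathway, "pathway_definition"))
  new_ids <- vapply(pathway$reactions, `[[`, character(1), "id")
  clash <- new_ids %in% model$rxns
  if (any(clash)) stop("pathway reaction id collides with host model: ",
                       paste(new_ids[clash], collapse = ", "))
  if (anyDuplicated(new_ids)) stop("duplicate pathway reaction ids")
  referenced <- unique(unlist(lapply(pathway$reactions,
                                     function(r) names(r$coeffs))))
  unknown <- setdiff(referenced, c(model$mets, pathway$new_metabolites))
  if (length(unknown)) stop("pathway references undeclared metabolites: ",
                            paste(unknown, collapse = ", "))
  add_mets <- setdiff(intersect(referenced, pathway$new_metabolites),
                      model$mets)
  mets <- c(model$mets, add_mets)
  Sold <- rbind(model$S,
                Matrix::Matrix(0, length(add_mets), length(model$rxns),
                               sparse = TRUE))
  Snew <- Matrix::Matrix(0, length(mets), length(new_ids), sparse = TRUE)
  rownames(Sold) <- mets
  dimnames(Snew) <- list(mets, new_ids)
  for (k in seq_along(pathway$reactions)) {
    r <- pathway$reactions[[k]]
    Snew[names(r$coeffs), k] <- r$coeffs
  }
  S <- cbind(Sold, Snew)
  lb <- c(model$lb, vapply(pathway$reactions, `[[`, numeric(1), "lb"))
  ub <- c(model$ub, vapply(pathway$reactions, `[[`, numeric(1), "ub"))
  cat_new <- vapply(pathway$reactions, function(r) {
    if (!is.null(r$category)) r$category else NA_character_
  }, character(1))
  category <- c(model$category, cat_new)
  gene <- c(model$gene_associated, rep(TRUE, length(new_ids)))
  out <- metabolic_network(S, lb, ub, model$growth_reaction,
                           gene_associated = gene, category = category,
                           product_exchange = model$product_exchange,
                           met_base = c(model$met_base,
                                        sub("\\[[^][]*\\]$", "", add_mets)))
  if (is.null(out$product_exchange)) {
    new_pos <- match(new_ids, out$rxns)
    ex <- new_ids[out$category[new_pos] == "exchange"]
    if (length(ex)) out$product_exchange <- ex[length(ex)]
  }
  out
}

# ---------------------------------------------------------------------------
# bound edits

#' Read bound edits from TSV
#'
#' Columns: `reaction_id`, `lb`, `ub`.
#' @param path TSV file path.
#' @return a data frame of edits.
#' @export
read_bound_edits <- function(path) {
  if (!file.exists(path)) stop("bound-edit file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  req <- c("reaction_id", "lb", "ub")
  if (!all(req %in% names(tab))) {
    stop("bound-edit file must have columns: ", paste(req, collapse = ", "))
  }
  tab
}

#' Apply bound edits to a model
#'
#' @param model a `metabolic_network`.
#' @param edits data frame with columns `reaction_id`, `lb`, `ub`.
#' @return the edited model (a copy).
#' @export
apply_bound_edits <- function(model, edits) {
  idx <- match(edits$reaction_id, model$rxns)
  if (anyNA(idx)) stop("unknown reaction in bound edits: ",
                       paste(edits$reaction_id[is.na(idx)], collapse = ", "))
  if (any(edits$lb > edits$ub)) stop("bound edit with lb > ub")
  model$lb[idx] <- edits$lb
  model$ub[idx] <- edits$ub
  model
}

# ---------------------------------------------------------------------------
# constrained views

#' Apply knockouts and a chemical environment to a model
#'
#' Returns an immutable "view": a copy of the model in which knocked-out
#' reactions have bounds `[0, 0]`, the selected environment components'
#' exchanges are opened for uptake to the environment's bound magnitude and
#' forced to carry uptake (flux <= -1), and unselected candidate exchanges
#' are closed for uptake.  Base-open exchanges (minerals, oxygen, water,
#' ...) are left untouched.  The base model is never modified.
#'
#' @param model a `metabolic_network`.
#' @param knockouts character vector of reaction ids to disable.
#' @param environment character vector of selected components: exchange
#'   reaction ids or component names from `env_space`.
#' @param env_space a [chemical_environment_space()].
#' @return a `metabolic_network` with `knockouts` and `environment` fields
#'   recording the view.
#' @export
apply_constraints <- function(model, knockouts = character(0),
                              environment = character(0), env_space) {
  stopifnot(inherits(model, "metabolic_network"))
  unknown <- setdiff(knockouts, model$rxns)
  if (length(unknown)) stop("unknown knockout reaction: ",
                            paste(unknown, collapse = ", "))
  env_ids <- resolve_env_components(environment, env_space)
  view <- model
  cand_ids <- env_space$candidates$exchange_id
  missing <- setdiff(cand_ids, model$rxns)
  if (length(missing)) stop("candidate exchange not in model: ",
                            paste(missing, collapse = ", "))
  ci <- match(cand_ids, model$rxns)
  # close all candidate uptakes, then open the selected ones
  view$lb[ci] <- pmax(view$lb[ci], 0)
  sel <- match(env_ids, model$rxns)
  view$lb[sel] <- -env_space$uptake_bound_magnitude
  view$ub[sel] <- pmin(view$ub[sel], -1)
  ki <- match(knockouts, model$rxns)
  view$lb[ki] <- 0
  view$ub[ki] <- 0
  view$knockouts <- sort(unique(knockouts))
  view$environment <- sort(env_ids)
  view
}

resolve_env_components <- function(environment, env_space) {
  if (length(environment) == 0L) return(character(0))
  cand <- env_space$candidates
  ids <- ifelse(environment %in% cand$exchange_id, environment,
                cand$exchange_id[match(environment, cand$component)])
  if (anyNA(ids)) {
    stop("environment component not among candidates: ",
         paste(environment[is.na(ids)], collapse = ", "))
  }
  unique(ids)
}

#' Define the chemical-environment search space
#'
#' @param candidates data frame with columns `component`, `exchange_id`,
#'   `role` (one of `carbon`, `nitrogen`, `other`).
#' @param base_open exchange ids that stay open in every environment
#'   (minerals, oxygen, water, protons, phosphate, sulfate).
#' @param uptake_bound_magnitude magnitude to which a selected component's
#'   uptake is opened.
#' @return an object of class `chemical_environment_space`.
#' @export
chemical_environment_space <- function(candidates,
                                       base_open = character(0),
                                       uptake_bound_magnitude = 1000) {
  stopifnot(is.data.frame(candidates),
            all(c("component", "exchange_id", "role") %in%
                  names(candidates)),
            uptake_bound_magnitude > 0)
  if (length(intersect(candidates$exchange_id, base_open))) {
    stop("candidate and base-open exchange sets must be disjoint")
  }
  structure(list(candidates = candidates, base_open = base_open,
                 uptake_bound_magnitude = uptake_bound_magnitude),
            class = "chemical_environment_space")
}

#' Check an environment space against a model
#'
#' Verifies that every candidate and base-open exchange id exists and is
#' exchange-tagged.
#' @param env_space a [chemical_environment_space()].
#' @param model a `metabolic_network`.
#' @return the space, invisibly; errors on violation.
#' @export
validate_env_space <- function(env_space, model) {
  ids <- c(env_space$candidates$exchange_id, env_space$base_open)
  idx <- match(ids, model$rxns)
  if (anyNA(idx)) stop("exchange id not in model: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  not_ex <- model$category[idx] != "exchange"
  if (any(not_ex)) stop("environment id not exchange-tagged: ",
                        paste(ids[not_ex], collapse = ", "))
  invisible(env_space)
}
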