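# Readers and writers: the tabular model dialect, an SBML Level 3 (+ flux
# bounds) subset, community configuration files, and result serialisation.
# Floats are written with 15 significant digits so numeric round trips
# stay within 1e-12 even for O(1) quantities.

FMT <- function(x) formatC(x, digits = 15, format = "g")

#' Write a species model in the tabular dialect
#'
#' Two TSV files: `<species>_metabolites.tsv` (id, name, role, formula,
#' charge) and `<species>_reactions.tsv` (reaction_id, kind, equation,
#' lb, ub).
#'
#' @param sm A `species_model`.
#' @param dir Output directory.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_species_tsv <- function(sm, dir) {
  stopifnot(inherits(sm, "species_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mpath <- file.path(dir, paste0(sm$species_id, "_metabolites.tsv"))
  rpath <- file.path(dir, paste0(sm$species_id, "_reactions.tsv"))
  utils::write.table(sm$metabolites, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  r <- sm$reactions
  rt <- tibble(reaction_id = r$id, kind = r$kind,
               equation = map_chr(r$id, function(id) format_equation(sm$stoich[[id]])),
               lb = FMT(r$lb), ub = FMT(r$ub))
  utils::write.table(rt, rpath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(metabolites = mpath, reactions = rpath))
}

#' Read a species model from the tabular dialect
#'
#' @param species_id Species identifier.
#' @param metabolites_path,reactions_path Paths to the two TSV files
#'   written by [write_species_tsv()].
#' @return A `species_model`.
#' @export
read_species_tsv <- function(species_id, metabolites_path, reactions_path) {
  for (p in c(metabolites_path, reactions_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  mets <- utils::read.delim(metabolites_path, na.strings = c("NA", ""),
                            colClasses = "character")
  mets$charge <- suppressWarnings(as.numeric(mets$charge))
  rxns <- utils::read.delim(reactions_path, na.strings = c("NA", ""),
                            colClasses = "character")
  species_model(species_id,
                as_tibble(mets),
                tibble(id = rxns$reaction_id, kind = rxns$kind,
                       equation = rxns$equation,
                       lb = as.numeric(rxns$lb), ub = as.numeric(rxns$ub)))
}

# ---- SBML Level 3 (+ fbc-style flux bounds) subset -------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
ROLE_NS <- "https://cfba.r-lib.org/ns/roles"

#' Write a species model as SBML Level 3 with flux bounds
#'
#' Emits an SBML Level 3 Version 1 document with the flux-balance (fbc v2)
#' constructs this package consumes: two compartments (`c` intracellular,
#' `e` extracellular), species with chemical formulas and charges, global
#' parameters holding the flux bounds referenced per reaction, and an
#' objective marking the biomass reaction. Metabolite roles and reaction
#' kinds are recorded in a package annotation namespace so a round trip is
#' lossless; readers of plain SBML ignore them.
#'
#' @param sm A `species_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_species_sbml <- function(sm, path) {
  stopifnot(inherits(sm, "species_model"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" xmlns:cfba="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS, ROLE_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(sm$species_id)),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '      <compartment id="e" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (k in seq_len(nrow(sm$metabolites))) {
    m <- sm$metabolites[k, ]
    comp <- if (m$role == "intracellular") "c" else "e"
    attrs <- sprintf('id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" cfba:role="%s"',
                     esc(m$id), esc(m$name), comp, m$role)
    if (!is.na(m$formula)) attrs <- paste(attrs, sprintf('fbc:chemicalFormula="%s"', m$formula))
    if (!is.na(m$charge)) attrs <- paste(attrs, sprintf('fbc:charge="%d"', as.integer(m$charge)))
    lines <- c(lines, sprintf('      <species %s/>', attrs))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (k in seq_len(nrow(sm$reactions))) {
    r <- sm$reactions[k, ]
    lines <- c(lines,
               sprintf('      <parameter id="lb_%s" value="%s" constant="true"/>', esc(r$id), FMT(r$lb)),
               sprintf('      <parameter id="ub_%s" value="%s" constant="true"/>', esc(r$id), FMT(r$ub)))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (k in seq_len(nrow(sm$reactions))) {
    r <- sm$reactions[k, ]
    st <- sm$stoich[[r$id]]
    lines <- c(lines, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s" cfba:kind="%s">',
      esc(r$id), tolower(as.character(r$lb < 0)), esc(r$id), esc(r$id), r$kind))
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lines <- c(lines, '        <listOfReactants>',
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         esc(names(subs)), FMT(abs(subs))),
                 '        </listOfReactants>')
    }
    if (length(prods)) {
      lines <- c(lines, '        <listOfProducts>',
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         esc(names(prods)), FMT(prods)),
                 '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines,
             '    </listOfReactions>',
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             '        <fbc:listOfFluxObjectives>',
             sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>', esc(sm$biomass_id)),
             '        </fbc:listOfFluxObjectives>',
             '      </fbc:objective>',
             '    </fbc:listOfObjectives>',
             '  </model>',
             '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

#' Read a species model from SBML Level 3
#'
#' Accepts the subset written by [write_species_sbml()] and, with reduced
#' fidelity, plain SBML Level 3 documents: flux bounds are taken from
#' fbc-style bound attributes referencing parameters and default to
#' (-1000, 1000) for reversible and (0, 1000) for irreversible reactions
#' (with a warning) when absent; the biomass reaction is identified from
#' the active fbc objective or, failing that, by an id/name matching
#' `biomass|growth` (two matches is an error). Metabolite roles come from
#' the package's annotation attributes when present, otherwise
#' compartment `e` species are `"unique"` unless listed in
#' `crossfed_ids`.
#'
#' @param path SBML file path.
#' @param species_id Species identifier; defaults to the SBML model id.
#' @param crossfed_ids Extracellular metabolites to classify as crossfed
#'   when the file does not carry role annotations.
#' @return A `species_model`.
#' @export
read_species_sbml <- function(path, species_id = NULL, crossfed_ids = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("cannot parse SBML file '%s': %s", path, conditionMessage(e)))
  })
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (is.na(xml2::xml_name(model))) abort("no <model> element found")
  species_id <- species_id %||% xml2::xml_attr(model, "id")
  if (is.na(species_id) || !nzchar(species_id)) abort("model has no id; pass species_id")

  # compartments tagged extracellular by id/name convention
  comps <- xml2::xml_find_all(model, ".//listOfCompartments/compartment")
  comp_ids <- xml2::xml_attr(comps, "id")
  comp_names <- xml2::xml_attr(comps, "name")
  comp_names[is.na(comp_names)] <- ""
  ext_comp <- comp_ids[grepl("^e$|extern|extracell|_e$", comp_ids, ignore.case = TRUE) |
                         grepl("extern|extracell", comp_names, ignore.case = TRUE)]

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  sid <- xml2::xml_attr(sp_nodes, "id")
  scomp <- xml2::xml_attr(sp_nodes, "compartment")
  srole <- xml2::xml_attr(sp_nodes, "role")
  sname <- xml2::xml_attr(sp_nodes, "name")
  sform <- xml2::xml_attr(sp_nodes, "chemicalFormula")
  scharge <- suppressWarnings(as.numeric(xml2::xml_attr(sp_nodes, "charge")))
  role <- ifelse(!is.na(srole), srole,
                 ifelse(scomp %in% ext_comp,
                        ifelse(sid %in% (crossfed_ids %||% character(0)),
                               "crossfed", "unique"),
                        "intracellular"))
  mets <- tibble(id = sid, name = ifelse(is.na(sname), sid, sname),
                 role = role, formula = sform, charge = scharge)

  params <- xml2::xml_find_all(model, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0) abort("model has no reactions")
  missing_bounds <- FALSE
  rxns <- map(rx_nodes, function(nd) {
    rid <- xml2::xml_attr(nd, "id")
    rev <- identical(xml2::xml_attr(nd, "reversible"), "true")
    lbref <- xml2::xml_attr(nd, "lowerFluxBound")
    ubref <- xml2::xml_attr(nd, "upperFluxBound")
    lb <- if (!is.na(lbref) && lbref %in% names(pval)) pval[[lbref]] else NA_real_
    ub <- if (!is.na(ubref) && ubref %in% names(pval)) pval[[ubref]] else NA_real_
    if (is.na(lb)) { lb <- if (rev) -1000 else 0; missing_bounds <<- TRUE }
    if (is.na(ub)) { ub <- 1000; missing_bounds <<- TRUE }
    get_side <- function(xp, sign) {
      refs <- xml2::xml_find_all(nd, xp)
      if (!length(refs)) return(numeric(0))
      stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      xml2::xml_attr(refs, "species"))
    }
    st <- c(get_side(".//listOfReactants/speciesReference", -1),
            get_side(".//listOfProducts/speciesReference", +1))
    if (length(st) == 0) abort(sprintf("reaction '%s' has no participants", rid))
    st <- tapply(st, names(st), sum)
    list(id = rid, kind = xml2::xml_attr(nd, "kind"), lb = lb, ub = ub,
         stoich = st[st != 0])
  })
  if (missing_bounds) {
    warn(sprintf("'%s': flux bounds missing for some reactions; defaults applied", path))
  }

  # biomass: active objective, else name pattern
  fobj <- xml2::xml_find_all(model, ".//listOfObjectives//fluxObjective")
  biomass_ids <- unique(xml2::xml_attr(fobj, "reaction"))
  biomass_ids <- biomass_ids[!is.na(biomass_ids)]
  rids <- map_chr(rxns, "id")
  if (length(biomass_ids) == 0) {
    rnames <- xml2::xml_attr(rx_nodes, "name")
    hit <- grepl("biomass|growth", rids, ignore.case = TRUE) |
      (!is.na(rnames) & grepl("biomass|growth", rnames, ignore.case = TRUE))
    biomass_ids <- rids[hit]
  }
  if (length(biomass_ids) == 0) abort("no biomass reaction identifiable (no objective, no name match)")
  if (length(biomass_ids) > 1) {
    abort(sprintf("multiple biomass-flagged reactions: %s", paste(biomass_ids, collapse = ", ")))
  }

  role_of <- stats::setNames(mets$role, mets$id)
  rx_tbl <- bind_rows(map(rxns, function(r) {
    kind <- r$kind
    if (is.na(kind)) {
      roles <- role_of[names(r$stoich)]
      kind <- if (r$id == biomass_ids) "biomass"
        else if (all(roles == "intracellular")) "intracellular"
        else if (any(roles == "crossfed")) "crossfeed_transport"
        else "unique_transport"
    }
    tibble(id = r$id, kind = kind,
           equation = format_equation(r$stoich), lb = r$lb, ub = r$ub)
  }))
  species_model(species_id, mets, rx_tbl)
}

# ---- community configuration -----------------------------------------------

#' Read a community configuration file
#'
#' JSON or YAML (by extension). Schema:
#' \preformatted{
#' species:           list of {id, metabolites, reactions} (tabular) or
#'                    {id (optional), sbml} entries; paths relative to the
#'                    config file
#' crossfed:          list of extracellular metabolite ids
#' exchanges:         list of {metabolite, J_lb, J_ub} (mmol/h), optional
#' X_T:               total biomass, gDW (default 1)
#' fixed_mu:          optional growth rate to hold (chemostat dilution rate)
#' extra_constraints: optional list of {terms: {flux: coef, ...}, sense, rhs}
#' }
#'
#' @param path Config file path.
#' @return A validated `community_config` list.
#' @export
read_community_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  base <- dirname(normalizePath(path))
  fail <- function(field, msg) abort(sprintf("config %s: %s", field, msg))

  if (is.null(cfg$species) || length(cfg$species) < 1) fail("species", "at least one species required")
  species <- imap(cfg$species, function(s, k) {
    field <- sprintf("species[%s]", k)
    if (!is.null(s$sbml)) {
      p <- file.path(base, s$sbml)
      if (!file.exists(p)) fail(paste0(field, ".sbml"), sprintf("file not found: %s", s$sbml))
      list(id = s$id %||% NULL, sbml = p)
    } else {
      for (fld in c("id", "metabolites", "reactions")) {
        if (is.null(s[[fld]])) fail(paste0(field, ".", fld), "missing")
      }
      mp <- file.path(base, s$metabolites); rp <- file.path(base, s$reactions)
      if (!file.exists(mp)) fail(paste0(field, ".metabolites"), sprintf("file not found: %s", s$metabolites))
      if (!file.exists(rp)) fail(paste0(field, ".reactions"), sprintf("file not found: %s", s$reactions))
      list(id = s$id, metabolites = mp, reactions = rp)
    }
  })
  X_T <- cfg$X_T %||% 1
  if (!is.numeric(X_T) || X_T <= 0) fail("X_T", "must be a positive number")
  fixed_mu <- cfg$fixed_mu
  if (!is.null(fixed_mu) && (!is.numeric(fixed_mu) || fixed_mu < 0)) {
    fail("fixed_mu", "must be a non-negative number")
  }
  exchanges <- NULL
  if (!is.null(cfg$exchanges)) {
    exchanges <- bind_rows(imap(cfg$exchanges, function(e, k) {
      field <- sprintf("exchanges[%s]", k)
      for (fld in c("metabolite", "J_lb", "J_ub")) {
        if (is.null(e[[fld]])) fail(paste0(field, ".", fld), "missing")
      }
      if (e$J_lb > e$J_ub) fail(field, "J_lb exceeds J_ub")
      tibble(metabolite_id = e$metabolite, J_lb = e$J_lb, J_ub = e$J_ub)
    }))
  }
  extra <- NULL
  if (!is.null(cfg$extra_constraints)) {
    extra <- imap(cfg$extra_constraints, function(ec, k) {
      field <- sprintf("extra_constraints[%s]", k)
      if (is.null(ec$terms) || !length(ec$terms)) fail(paste0(field, ".terms"), "missing")
      list(terms = unlist(ec$terms), sense = ec$sense %||% "<=", rhs = ec$rhs %||% 0)
    })
  }
  structure(
    list(species = species,
         crossfed = as.character(unlist(cfg$crossfed %||% list())),
         exchanges = exchanges,
         X_T = X_T, fixed_mu = fixed_mu,
         extra_constraints = extra,
         path = normalizePath(path)),
    class = "community_config")
}

#' Build a community model from a configuration
#'
#' @param cfg A `community_config` from [read_community_config()].
#' @return A `community_model`.
#' @export
build_community_from_config <- function(cfg) {
  stopifnot(inherits(cfg, "community_config"))
  species <- map(cfg$species, function(s) {
    if (!is.null(s$sbml)) {
      read_species_sbml(s$sbml, species_id = s$id, crossfed_ids = cfg$crossfed)
    } else {
      read_species_tsv(s$id, s$metabolites, s$reactions)
    }
  })
  assemble_community(species, crossfed_ids = cfg$crossfed,
                     env_exchanges = cfg$exchanges, X_T = cfg$X_T)
}

# ---- results ---------------------------------------------------------------

#' Write a balanced-growth solution to TSV or JSON
#'
#' TSV holds the flux table (one row per flux, plus a `mu` row); JSON
#' holds status, growth rate, fractions and fluxes. Infeasible or
#' unbounded solutions serialise their status and no fluxes.
#'
#' @param sol A `balanced_growth_solution`.
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_solution <- function(sol, path, format = c("tsv", "json")) {
  stopifnot(inherits(sol, "balanced_growth_solution"))
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(status = sol$status)
    if (sol$status == "optimal") {
      obj$mu <- sol$mu
      obj$objective_value <- sol$objective_value
      obj$f <- as.list(sol$f)
      obj$fluxes <- stats::setNames(as.list(sol$fluxes$value), sol$fluxes$flux)
      obj$binding <- sol$binding$flux
    }
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    hdr <- c(sprintf("# status\t%s", sol$status),
             sprintf("# f\t%s", paste(sprintf("%s=%s", names(sol$f), FMT(sol$f)),
                                      collapse = ",")))
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    if (sol$status == "optimal") {
      tb <- sol$fluxes
      writeLines("flux\ttype\tspecies\treaction\tvalue", con)
      writeLines(sprintf("%s\t%s\t%s\t%s\t%s", tb$flux, tb$type,
                         ifelse(is.na(tb$species), "", tb$species),
                         ifelse(is.na(tb$reaction), "", tb$reaction),
                         FMT(tb$value)), con)
    }
  }
  invisible(path)
}

#' Read back a solution written by [write_solution()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return A list with `status` and, when optimal, `mu`, `f` and a
#'   named `fluxes` vector.
#' @export
read_solution <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    out <- list(status = obj$status)
    if (identical(obj$status, "optimal")) {
      out$mu <- obj$mu
      out$f <- unlist(obj$f)
      out$fluxes <- unlist(obj$fluxes)
    }
    return(out)
  }
  lines <- readLines(path)
  status <- sub("^# status\t", "", lines[1])
  fline <- sub("^# f\t", "", lines[2])
  fparts <- strsplit(strsplit(fline, ",")[[1]], "=")
  f <- stats::setNames(as.numeric(map_chr(fparts, 2)), map_chr(fparts, 1))
  out <- list(status = status, f = f)
  if (status == "optimal") {
    tb <- utils::read.delim(text = lines[-(1:2)])
    out$mu <- tb$value[tb$flux == "mu"]
    out$fluxes <- stats::setNames(tb$value, tb$flux)
  }
  out
}

#' Write a fraction scan as TSV
#'
#' One row per grid point: the fraction columns, `mu`, `status` (and
#' `ratio` for biomass-ratio scans) — ready for line or contour plotting.
#'
#' @param scan A `fraction_scan`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  stopifnot(inherits(scan, "fraction_scan"))
  utils::write.table(scan$grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a phase plane as long-format TSV
#'
#' @param pp A `phase_plane`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phase_plane_tsv <- function(pp, path) {
  stopifnot(inherits(pp, "phase_plane"))
  utils::write.table(pp$grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a cross-feeding screen report as TSV, ranked by percent change
#'
#' @param sr A `screen_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(sr, path) {
  stopifnot(inherits(sr, "screen_result"))
  tb <- sr$table[order(sr$table$percent_change), ]
  utils::write.table(tb, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
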