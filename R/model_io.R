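#' Read a genome-scale metabolic model
#'
#' Supports two on-disk representations:
#' \describe{
#'   \item{`sbml`}{An SBML subset covering Level 2 (COBRA dialect: bounds as
#'     `LOWER_BOUND`/`UPPER_BOUND` kinetic-law parameters, gene associations
#'     in `GENE_ASSOCIATION:` notes) and Level 3 core with the `fbc`
#'     extension (flux bounds as parameter references, gene associations as
#'     `fbc:geneProductAssociation`, objective via `fbc:listOfObjectives`).}
#'   \item{`tsv`}{A flat dialect: a directory holding `reactions.tsv`
#'     (id, name, equation, lb, ub, subsystem, gpr, objective — equation as
#'     `"1 A + 2 B -> 1 C"`, `<=>` for reversible) and `metabolites.tsv`
#'     (id, name, compartment, optional boundary).}
#' }
#' Bounds absent from the file default to (-1000, 1000) for reversible and
#' (0, 1000) for irreversible reactions (COBRA convention). Metabolites with
#' `boundaryCondition="true"` or an `_b` id suffix are flagged boundary and
#' excluded from mass-balance rows.
#'
#' @param path file (SBML) or directory (TSV).
#' @param format `"sbml"` or `"tsv"`; guessed from `path` when omitted.
#' @return a validated [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "sbml", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "tsv" else "sbml"
  }
  if (!file.exists(path)) stop("no such file or directory: ", path)
  model <- switch(format,
                  sbml = read_model_sbml(path),
                  tsv = read_model_tsv(path))
  bad <- validate_model(model)
  if (length(bad)) stop("invalid model in ", path, ":\n  ", paste(bad, collapse = "\n  "))
  model
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in ", path, ": ",
                                           conditionMessage(e)))
  find <- function(node, xp) xml2::xml_find_all(node, xp)
  loc <- function(tag) paste0("*[local-name()='", tag, "']")
  mnode <- find(doc, paste0("./", loc("model")))
  if (length(mnode) != 1L) stop("SBML parse error in ", path, ": no <model> element")
  mnode <- mnode[[1L]]
  model_id <- xml2::xml_attr(mnode, "id")
  if (is.na(model_id)) model_id <- "model"

  attr_of <- function(nd, name, default = NA_character_) {
    a <- xml2::xml_attrs(nd)
    hit <- which(names(a) == name | grepl(paste0(":", name, "$"), names(a)))
    if (length(hit)) unname(a[hit[1L]]) else default
  }

  ## parameters (L3/fbc bound references)
  pnodes <- find(mnode, paste0("./", loc("listOfParameters"), "/", loc("parameter")))
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(pnodes, "value")),
                           xml2::xml_attr(pnodes, "id"))

  ## gene products (fbc): id -> label
  gnodes <- find(mnode, paste0(".//", loc("listOfGeneProducts"), "/", loc("geneProduct")))
  glab <- character(0)
  if (length(gnodes)) {
    gid <- vapply(gnodes, attr_of, character(1), name = "id")
    glb <- vapply(gnodes, attr_of, character(1), name = "label")
    glab <- stats::setNames(ifelse(is.na(glb), gid, glb), gid)
  }

  ## species
  snodes <- find(mnode, paste0("./", loc("listOfSpecies"), "/", loc("species")))
  if (!length(snodes)) stop("SBML parse error in ", path, ": no species declared")
  sid <- xml2::xml_attr(snodes, "id")
  sname <- xml2::xml_attr(snodes, "name"); sname[is.na(sname)] <- sid[is.na(sname)]
  scomp <- xml2::xml_attr(snodes, "compartment"); scomp[is.na(scomp)] <- "c"
  sbc <- tolower(xml2::xml_attr(snodes, "boundaryCondition"))
  boundary <- (!is.na(sbc) & sbc == "true") | grepl("_b$", sid)
  metabolites <- data.frame(id = sid, name = sname, compartment = scomp,
                            boundary = boundary, stringsAsFactors = FALSE)

  ## fbc objective
  obj_rxn <- character(0); obj_coef <- numeric(0)
  fo <- find(mnode, paste0(".//", loc("listOfFluxObjectives"), "/", loc("fluxObjective")))
  if (length(fo)) {
    obj_rxn <- vapply(fo, attr_of, character(1), name = "reaction")
    oc <- vapply(fo, attr_of, character(1), name = "coefficient")
    obj_coef <- ifelse(is.na(oc), 1, as.numeric(oc))
  }

  rnodes <- find(mnode, paste0("./", loc("listOfReactions"), "/", loc("reaction")))
  nr <- length(rnodes)
  rid <- character(nr); rname <- character(nr); rlb <- numeric(nr); rub <- numeric(nr)
  rsub <- character(nr); robj <- numeric(nr)
  stoich <- vector("list", nr); gpr <- vector("list", nr)
  for (i in seq_len(nr)) {
    nd <- rnodes[[i]]
    rid[i] <- xml2::xml_attr(nd, "id")
    nm <- xml2::xml_attr(nd, "name"); rname[i] <- if (is.na(nm)) rid[i] else nm
    rev <- tolower(xml2::xml_attr(nd, "reversible"))
    reversible <- is.na(rev) || rev == "true"   # SBML L2 default: reversible

    st <- numeric(0)
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- find(nd, paste0("./", loc(tag), "/", loc("speciesReference")))
      if (length(refs)) {
        sp <- xml2::xml_attr(refs, "species")
        co <- xml2::xml_attr(refs, "stoichiometry")
        co <- ifelse(is.na(co), 1, as.numeric(co))
        for (k in seq_along(sp)) st[sp[k]] <- (if (is.na(st[sp[k]])) 0 else st[sp[k]]) + side * co[k]
        st <- st[!is.na(st)]
      }
    }
    stoich[[i]] <- st[st != 0]

    ## bounds: L2 kinetic-law parameters, else fbc parameter refs, else defaults
    lb <- NA_real_; ub <- NA_real_; oc <- NA_real_
    kp <- find(nd, paste0("./", loc("kineticLaw"), "//", loc("parameter")))
    if (length(kp)) {
      pid <- xml2::xml_attr(kp, "id"); pid[is.na(pid)] <- xml2::xml_attr(kp, "name")[is.na(pid)]
      pv <- as.numeric(xml2::xml_attr(kp, "value"))
      kv <- stats::setNames(pv, toupper(pid))
      if ("LOWER_BOUND" %in% names(kv)) lb <- kv[["LOWER_BOUND"]]
      if ("UPPER_BOUND" %in% names(kv)) ub <- kv[["UPPER_BOUND"]]
      if ("OBJECTIVE_COEFFICIENT" %in% names(kv)) oc <- kv[["OBJECTIVE_COEFFICIENT"]]
    }
    flb <- attr_of(nd, "lowerFluxBound"); fub <- attr_of(nd, "upperFluxBound")
    if (is.na(lb) && !is.na(flb) && flb %in% names(pvals)) lb <- pvals[[flb]]
    if (is.na(ub) && !is.na(fub) && fub %in% names(pvals)) ub <- pvals[[fub]]
    rlb[i] <- if (is.na(lb)) (if (reversible) -1000 else 0) else lb
    rub[i] <- if (is.na(ub)) 1000 else ub
    robj[i] <- if (!is.na(oc)) oc else if (rid[i] %in% obj_rxn) obj_coef[match(rid[i], obj_rxn)] else 0

    ## GPR: fbc geneProductAssociation, else GENE_ASSOCIATION note
    gpa <- find(nd, paste0("./", loc("geneProductAssociation")))
    if (length(gpa)) {
      gpr[[i]] <- sbml_parse_gpa(xml2::xml_children(gpa[[1L]])[[1L]], glab)
    } else {
      ## one line per <p>/<html:p>; fall back to raw text split on newlines
      pnotes <- find(nd, paste0("./", loc("notes"), "//", loc("p")))
      notes <- if (length(pnotes)) xml2::xml_text(pnotes) else
        strsplit(paste(xml2::xml_text(find(nd, paste0("./", loc("notes")))),
                       collapse = "\n"), "\n")[[1]]
      ga <- regmatches(notes, regexpr("GENE[ _]ASSOCIATION:[^\n<]*", notes, perl = TRUE))
      ga <- ga[nzchar(ga)]
      if (length(ga) && nzchar(ga[1L])) {
        gpr[i] <- list(parse_gpr(sub("GENE[ _]ASSOCIATION:", "", ga[1L])))
      }
      sub_note <- regmatches(notes, regexpr("SUBSYSTEM:[^\n<]*", notes, perl = TRUE))
      if (length(sub_note)) rsub[i] <- trimws(sub("SUBSYSTEM:", "", sub_note[1L]))
    }
  }
  names(stoich) <- rid; names(gpr) <- rid
  reactions <- data.frame(id = rid, name = rname, lb = rlb, ub = rub,
                          subsystem = rsub, objective = robj,
                          stringsAsFactors = FALSE)
  metabolic_model(model_id, metabolites, reactions, stoich, gpr)
}

sbml_parse_gpa <- function(node, glab) {
  tag <- xml2::xml_name(node)
  if (grepl("geneProductRef", tag)) {
    a <- xml2::xml_attrs(node)
    hit <- which(grepl("geneProduct$", names(a)))
    gid <- unname(a[hit[1L]])
    return(if (gid %in% names(glab)) unname(glab[gid]) else gid)
  }
  kids <- lapply(xml2::xml_children(node), sbml_parse_gpa, glab = glab)
  if (grepl("and$", tag)) list(op = "and", args = kids)
  else if (grepl("or$", tag)) list(op = "or", args = kids)
  else stop("SBML parse error: unexpected element in gene association: ", tag)
}

read_model_tsv <- function(path) {
  rfile <- file.path(path, "reactions.tsv")
  mfile <- file.path(path, "metabolites.tsv")
  if (!file.exists(rfile) || !file.exists(mfile))
    stop("TSV model directory must contain reactions.tsv and metabolites.tsv: ", path)
  met <- utils::read.delim(mfile, stringsAsFactors = FALSE, check.names = FALSE)
  rxn <- utils::read.delim(rfile, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "equation")
  if (!all(need %in% names(rxn)))
    stop("reactions.tsv must have at least columns: ", paste(need, collapse = ", "))
  if (!"id" %in% names(met)) stop("metabolites.tsv must have an 'id' column")
  if (is.null(met$boundary)) met$boundary <- grepl("_b$", met$id)
  met$boundary <- as.logical(met$boundary)
  if (is.null(met$compartment)) met$compartment <- "c"

  n <- nrow(rxn)
  stoich <- vector("list", n); gpr <- vector("list", n)
  lb <- numeric(n); ub <- numeric(n)
  for (i in seq_len(n)) {
    eq <- parse_equation(rxn$equation[i], rxn$id[i])
    stoich[[i]] <- eq$stoich
    lb[i] <- if (!is.null(rxn$lb) && !is.na(rxn$lb[i])) rxn$lb[i] else if (eq$reversible) -1000 else 0
    ub[i] <- if (!is.null(rxn$ub) && !is.na(rxn$ub[i])) rxn$ub[i] else 1000
    if (!is.null(rxn$gpr)) gpr[i] <- list(parse_gpr(rxn$gpr[i]))
  }
  names(stoich) <- rxn$id; names(gpr) <- rxn$id
  reactions <- data.frame(
    id = rxn$id,
    name = if (is.null(rxn$name)) rxn$id else rxn$name,
    lb = lb, ub = ub,
    subsystem = if (is.null(rxn$subsystem)) "" else rxn$subsystem,
    objective = if (is.null(rxn$objective)) 0 else as.numeric(rxn$objective),
    stringsAsFactors = FALSE)
  metabolic_model(basename(normalizePath(path, mustWork = FALSE)),
                  met, reactions, stoich, gpr)
}

#' Parse a reaction equation string
#'
#' `"1 glc_c + 1 atp_c -> 1 g6p_c + 1 adp_c"`; coefficients default to 1,
#' `<=>` (or `<->`) marks a reversible reaction, an empty side is allowed for
#' exchange/drain reactions (`"glc_e ->"`).
#'
#' @param eq equation string.
#' @param rxn_id reaction id used in error messages.
#' @return list with `stoich` (signed named coefficients) and `reversible`.
#' @keywords internal
parse_equation <- function(eq, rxn_id = "?") {
  reversible <- grepl("<=>|<->", eq)
  sides <- strsplit(eq, "<=>|<->|-->|->", perl = TRUE)[[1]]
  if (length(sides) > 2L)
    stop("reaction ", rxn_id, ": malformed equation: ", eq)
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric(0))
    out <- numeric(0)
    for (term in strsplit(s, "\\s\\+\\s")[[1]]) {
      toks <- strsplit(trimws(term), "\\s+")[[1]]
      if (length(toks) == 1L) { coef <- 1; met <- toks }
      else if (length(toks) == 2L && !is.na(suppressWarnings(as.numeric(toks[1L])))) {
        coef <- as.numeric(toks[1L]); met <- toks[2L]
      } else stop("reaction ", rxn_id, ": malformed term '", term, "'")
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * coef
      out <- out[!is.na(out)]
    }
    out
  }
  lhs <- parse_side(sides[1L], -1)
  rhs <- if (length(sides) == 2L) parse_side(sides[2L], 1) else numeric(0)
  st <- lhs
  for (m in names(rhs)) st[m] <- (if (is.na(st[m])) 0 else st[m]) + rhs[m]
  st <- st[!is.na(st)]
  list(stoich = st[st != 0], reversible = reversible)
}

format_equation <- function(st) {
  fmt <- function(v) paste(sprintf("%g %s", abs(unname(v)), names(v)), collapse = " + ")
  lhs <- st[st < 0]; rhs <- st[st > 0]
  paste(if (length(lhs)) fmt(lhs) else "", "->", if (length(rhs)) fmt(rhs) else "")
}

#' Write a metabolic model
#'
#' Writing then reading back ([read_model()]) reproduces the model
#' structurally: same ids, bounds, stoichiometry and GPR boolean functions.
#' SBML output uses the Level 2 COBRA dialect (kinetic-law bound parameters,
#' `GENE_ASSOCIATION` notes) that the reader also accepts.
#'
#' @param model a `metabolic_model`.
#' @param path output file (SBML) or directory (TSV; created if missing).
#' @param format `"sbml"` or `"tsv"`.
#' @return invisibly, `path`.
#' @export
write_model <- function(model, path, format = c("sbml", "tsv")) {
  format <- match.arg(format)
  bad <- validate_model(model)
  if (length(bad)) stop("refusing to write invalid model:\n  ", paste(bad, collapse = "\n  "))
  if (format == "tsv") write_model_tsv(model, path) else write_model_sbml(model, path)
  invisible(path)
}

write_model_tsv <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  met <- model$metabolites[, c("id", "name", "compartment", "boundary")]
  utils::write.table(met, file.path(path, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rxn <- model$reactions
  eq <- vapply(model$stoichiometry, format_equation, character(1))
  ## render reversibility in the arrow for readability; bounds stay explicit
  eq <- ifelse(rxn$lb < 0, sub(" -> ", " <=> ", eq, fixed = TRUE), eq)
  out <- data.frame(id = rxn$id, name = rxn$name, equation = unname(eq),
                    lb = rxn$lb, ub = rxn$ub, subsystem = rxn$subsystem,
                    gpr = vapply(model$gpr, gpr_to_string, character(1)),
                    objective = rxn$objective, stringsAsFactors = FALSE)
  utils::write.table(out, file.path(path, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">')
  w('  <model id="', esc(model$id), '">')
  comps <- unique(model$metabolites$compartment)
  w('    <listOfCompartments>')
  for (cp in comps) w('      <compartment id="', esc(cp), '"/>')
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    w('      <species id="', esc(m$id), '" name="', esc(m$name),
      '" compartment="', esc(m$compartment),
      '" boundaryCondition="', tolower(as.character(m$boundary)), '"/>')
  }
  w('    </listOfSpecies>')
  w('    <listOfReactions>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[r$id]]
    w('      <reaction id="', esc(r$id), '" name="', esc(r$name),
      '" reversible="', tolower(as.character(r$lb < 0)), '">')
    gs <- gpr_to_string(model$gpr[[r$id]])
    w('        <notes><body xmlns="http://www.w3.org/1999/xhtml">')
    w('          <p>GENE_ASSOCIATION: ', esc(gs), '</p>')
    w('          <p>SUBSYSTEM: ', esc(r$subsystem), '</p>')
    w('        </body></notes>')
    lhs <- st[st < 0]; rhs <- st[st > 0]
    if (length(lhs)) {
      w('        <listOfReactants>')
      for (m in names(lhs))
        w('          <speciesReference species="', esc(m),
          '" stoichiometry="', format(abs(lhs[[m]]), digits = 15), '"/>')
      w('        </listOfReactants>')
    }
    if (length(rhs)) {
      w('        <listOfProducts>')
      for (m in names(rhs))
        w('          <speciesReference species="', esc(m),
          '" stoichiometry="', format(rhs[[m]], digits = 15), '"/>')
      w('        </listOfProducts>')
    }
    w('        <kineticLaw>')
    w('          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>')
    w('          <listOfParameters>')
    w('            <parameter id="LOWER_BOUND" value="', format(r$lb, digits = 15), '"/>')
    w('            <parameter id="UPPER_BOUND" value="', format(r$ub, digits = 15), '"/>')
    w('            <parameter id="OBJECTIVE_COEFFICIENT" value="',
      format(r$objective, digits = 15), '"/>')
    w('          </listOfParameters>')
    w('        </kineticLaw>')
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('  </model>')
  w('</sbml>')
}
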