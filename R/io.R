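## Format round-trips: schema-validated CSV artifacts, 16-bit TIFF
## images, and SBML Level 3 export/import of the seeding model.

.checkColumns <- function(df, need, path) {
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop(sprintf("%s: missing column(s) %s", path,
                     paste(miss, collapse = ", ")))
    for (col in setdiff(need, c("prep", "observable", "design_id",
                                "replicate", "class", "polarised"))) {
        v <- df[[col]]
        if (!is.numeric(v) || anyNA(v))
            stop(sprintf("%s: column '%s' must be numeric without NA",
                         path, col))
    }
    df[need]
}

#' Write / read a trajectory CSV
#'
#' Columns: \code{time_s}, \code{circulating_pol}, \code{circulating_dep},
#' \code{attached_pol}, \code{attached_dep}, \code{adhered_pol},
#' \code{adhered_dep}, \code{tissue}; one row per grid point. Per-arm
#' tissue attribution is an in-memory quantity and is not serialised.
#'
#' @param traj A \linkS4class{Trajectory}.
#' @param path File path.
#' @return \code{readTrajectoryCSV} returns a \linkS4class{Trajectory}
#'   (with per-arm tissue set to NA).
#' @export
writeTrajectoryCSV <- function(traj, path) {
    stopifnot(is(traj, "Trajectory"))
    utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @export
readTrajectoryCSV <- function(path) {
    df <- utils::read.csv(path)
    df <- .checkColumns(df, c("time_s", .compartments), path)
    if (any(diff(df$time_s) <= 0))
        stop(sprintf("%s: column 'time_s' must be strictly increasing",
                     path))
    states <- as.matrix(df[, .compartments])
    colnames(states) <- .compartments
    na <- matrix(NA_real_, nrow(df), 2,
                 dimnames = list(NULL, c("tissue_pol", "tissue_dep")))
    new("Trajectory", times = df$time_s, states = states, tissueByArm = na)
}

#' Write / read observation CSVs
#'
#' Columns: \code{design_id}, \code{time_s}, \code{observable},
#' \code{value}, \code{replicate} (the preparation label).
#'
#' @param observations Named list of \linkS4class{ObservationSet}s.
#' @param path File path.
#' @return \code{readObservationsCSV} returns a named list of
#'   \linkS4class{ObservationSet}s.
#' @export
writeObservationsCSV <- function(observations, path) {
    rows <- lapply(observations, function(o)
        data.frame(design_id = o@designId, time_s = o@data$time_s,
                   observable = o@data$observable, value = o@data$value,
                   replicate = o@data$prep))
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeObservationsCSV
#' @export
readObservationsCSV <- function(path) {
    df <- utils::read.csv(path)
    df <- .checkColumns(df, c("design_id", "time_s", "observable",
                              "value", "replicate"), path)
    out <- lapply(split(df, df$design_id), function(d)
        observationSet(d$design_id[1],
                       data.frame(prep = d$replicate,
                                  observable = d$observable,
                                  time_s = d$time_s, value = d$value)))
    out[order(names(out))]
}

#' Write / read boundary-profile CSVs
#'
#' Columns: \code{cell_id}, \code{bin_index}, \code{intensity} (long
#' format, one row per angular bin).
#'
#' @param profiles Numeric matrix, one profile per row.
#' @param path File path.
#' @return \code{readProfilesCSV} returns the profile matrix.
#' @export
writeProfilesCSV <- function(profiles, path) {
    df <- data.frame(cell_id = rep(seq_len(nrow(profiles)),
                                   each = ncol(profiles)),
                     bin_index = rep(seq_len(ncol(profiles)),
                                     nrow(profiles)),
                     intensity = as.numeric(t(profiles)))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeProfilesCSV
#' @export
readProfilesCSV <- function(path) {
    df <- utils::read.csv(path)
    df <- .checkColumns(df, c("cell_id", "bin_index", "intensity"), path)
    ids <- sort(unique(df$cell_id))
    nb <- max(df$bin_index)
    m <- matrix(NA_real_, length(ids), nb)
    for (j in seq_along(ids)) {
        d <- df[df$cell_id == ids[j], ]
        m[j, d$bin_index] <- d$intensity
    }
    if (anyNA(m)) stop(sprintf("%s: incomplete profiles", path))
    m
}

#' Write / read a depolarisation time-course CSV
#'
#' Columns: \code{time_h}, \code{fraction_polarised}, \code{n_cells}.
#'
#' @param course data.frame as from \code{\link{genDecayTimecourse}}.
#' @param path File path.
#' @export
writeTimecourseCSV <- function(course, path) {
    utils::write.csv(course[c("time_h", "fraction_polarised", "n_cells")],
                     path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTimecourseCSV
#' @export
readTimecourseCSV <- function(path) {
    df <- utils::read.csv(path)
    .checkColumns(df, c("time_h", "fraction_polarised", "n_cells"), path)
}

#' @rdname writeTimecourseCSV
#' @param calls data.frame as from \code{\link{callPoles}}.
#' @export
writeCallsCSV <- function(calls, path) {
    utils::write.csv(calls[c("cell_id", "polarised", "arc_start_frac",
                             "arc_len_frac", "enrichment")],
                     path, row.names = FALSE)
    invisible(path)
}

#' Write / read a 16-bit TIFF cell image
#'
#' Images are stored as 16-bit TIFF; intensities are divided by
#' \code{scale} on write and multiplied back on read, so any dynamic
#' range up to \code{scale} round-trips at 16-bit precision.
#'
#' @param image Numeric matrix of non-negative intensities.
#' @param path File path.
#' @param scale Full-scale intensity mapped to the 16-bit maximum.
#' @export
writeCellTIFF <- function(image, path, scale = 65535) {
    m <- pmin(pmax(image / scale, 0), 1)
    tiff::writeTIFF(m, path, bits.per.sample = 16L)
    invisible(path)
}

#' @rdname writeCellTIFF
#' @export
readCellTIFF <- function(path, scale = 65535) {
    m <- tiff::readTIFF(path)
    if (is.list(m)) m <- m[[1]]
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * scale
}

## ---- SBML Level 3 export / import -------------------------------------

.sbmlSpecies <- c(circulating_pol = "circulation",
                  circulating_dep = "circulation",
                  attached_pol = "substrate", attached_dep = "substrate",
                  adhered_pol = "substrate", adhered_dep = "substrate",
                  tissue = "tissue")

.sbmlReactions <- data.frame(
    id = c("attachment_pol", "attachment_dep", "adherence_pol",
           "adherence_dep", "tissue_residence_pol",
           "tissue_residence_dep"),
    reactant = c("circulating_pol", "circulating_dep", "attached_pol",
                 "attached_dep", "adhered_pol", "adhered_dep"),
    product = c("attached_pol", "attached_dep", "adhered_pol",
                "adhered_dep", "tissue", "tissue"),
    parameter = c("k_att_pol", "k_att_dep", "k_adh_pol", "k_adh_dep",
                  "k_tiss_pol", "k_tiss_dep"),
    stringsAsFactors = FALSE)

.sbmlParamOrder <- c("k_att_pol", "k_att_dep", "k_adh_pol", "k_adh_dep",
                     "k_tiss_pol", "k_tiss_dep")

#' Export / import the seeding model as SBML Level 3
#'
#' Writes the seven-species, six-reaction compartmental model as an SBML
#' Level 3 Version 2 document with mass-action kinetic laws
#' (\code{k * reactant}); \code{importSBML} parses such a document back
#' into rates and an initial state. Rates and initial amounts are written
#' at full double precision, so an export/import round trip reproduces
#' them exactly. Species may be expressed as counts or percentages; the
#' amounts are carried through unchanged and a \code{units} annotation
#' attribute records the choice.
#'
#' @param rates A \linkS4class{TransferRates}.
#' @param init Initial state (see \code{\link{compartmentState}}).
#' @param path Output file path.
#' @param units \code{"count"} or \code{"percent"} (metadata only).
#' @return \code{importSBML} returns a list with elements \code{rates},
#'   \code{init} and \code{units}.
#' @export
exportSBML <- function(rates, init, path, units = c("count", "percent")) {
    stopifnot(is(rates, "TransferRates"))
    units <- match.arg(units)
    s <- .asState(init)
    k <- rateVector(rates)
    names(k) <- .sbmlParamOrder
    num <- function(x) sprintf("%.17g", x)

    doc <- xml2::xml_new_root(
        "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
        level = "3", version = "2")
    model <- xml2::xml_add_child(doc, "model", id = "sc_polarity_seeding",
                                 name = "single-cell polarity seeding cascade")
    xml2::xml_set_attr(model, "substanceUnits", units)
    lc <- xml2::xml_add_child(model, "listOfCompartments")
    for (comp in c("circulation", "substrate", "tissue"))
        xml2::xml_add_child(lc, "compartment", id = comp, size = "1",
                            constant = "true")
    ls <- xml2::xml_add_child(model, "listOfSpecies")
    for (sp in names(.sbmlSpecies))
        xml2::xml_add_child(ls, "species", id = sp,
                            compartment = .sbmlSpecies[[sp]],
                            initialAmount = num(s[[sp]]),
                            hasOnlySubstanceUnits = "true",
                            boundaryCondition = "false",
                            constant = "false")
    lp <- xml2::xml_add_child(model, "listOfParameters")
    for (pn in .sbmlParamOrder)
        xml2::xml_add_child(lp, "parameter", id = pn,
                            value = num(k[[pn]]), constant = "true")
    lr <- xml2::xml_add_child(model, "listOfReactions")
    for (i in seq_len(nrow(.sbmlReactions))) {
        rx <- .sbmlReactions[i, ]
        rn <- xml2::xml_add_child(lr, "reaction", id = rx$id,
                                  reversible = "false")
        lre <- xml2::xml_add_child(rn, "listOfReactants")
        xml2::xml_add_child(lre, "speciesReference", species = rx$reactant,
                            stoichiometry = "1", constant = "true")
        lpr <- xml2::xml_add_child(rn, "listOfProducts")
        xml2::xml_add_child(lpr, "speciesReference", species = rx$product,
                            stoichiometry = "1", constant = "true")
        kl <- xml2::xml_add_child(rn, "kineticLaw")
        math <- xml2::xml_add_child(
            kl, "math", xmlns = "http://www.w3.org/1998/Math/MathML")
        ap <- xml2::xml_add_child(math, "apply")
        xml2::xml_add_child(ap, "times")
        xml2::xml_add_child(ap, "ci", rx$parameter)
        xml2::xml_add_child(ap, "ci", rx$reactant)
    }
    xml2::write_xml(doc, path)
    invisible(path)
}

#' @rdname exportSBML
#' @export
importSBML <- function(path) {
    doc <- tryCatch(xml2::read_xml(path), error = function(e)
        stop("malformed SBML document: ", conditionMessage(e)))
    ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core")
    model <- xml2::xml_find_first(doc, ".//s:model", ns)
    if (inherits(model, "xml_missing"))
        stop("malformed SBML document: no <model> element")
    spNodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
    if (length(spNodes) != 7)
        stop("expected 7 species, found ", length(spNodes))
    sv <- stats::setNames(
        as.numeric(xml2::xml_attr(spNodes, "initialAmount")),
        xml2::xml_attr(spNodes, "id"))
    if (!all(.compartments %in% names(sv)))
        stop("species ids do not match the seeding cascade compartments")
    pNodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter",
                                 ns)
    pv <- stats::setNames(as.numeric(xml2::xml_attr(pNodes, "value")),
                          xml2::xml_attr(pNodes, "id"))
    if (!all(.sbmlParamOrder %in% names(pv)))
        stop("missing rate parameter(s): ",
             paste(setdiff(.sbmlParamOrder, names(pv)), collapse = ", "))
    rNodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
    if (length(rNodes) != 6)
        stop("expected 6 reactions, found ", length(rNodes))
    k <- pv[.sbmlParamOrder]
    names(k) <- .rateNames
    units <- xml2::xml_attr(model, "substanceUnits")
    if (is.na(units)) units <- "count"
    list(rates = do.call(transferRates, as.list(k)),
         init = .asState(sv[.compartments]), units = units)
}
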