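#' Construct a ScoreTable
#'
#' @param moleculeIds character vector of unique molecule identifiers.
#' @param labels 0/1 (or logical) activity labels, 1 = active, 0 = decoy.
#' @param scores numeric matrix or data.frame of named score columns.
#' @param properties optional numeric matrix/data.frame of named positive
#'   property columns (e.g. \code{mw}, \code{heavy_atoms}).
#' @param source free-text provenance string.
#' @return A validated \linkS4class{ScoreTable}.
#' @examples
#' tab <- ScoreTable(c("m1", "m2", "m3"), c(1, 0, 0),
#'                   cbind(plp = c(-60, -40, -45), xscore = c(6.1, 5.0, 5.2)))
#' nActives(tab)
#' @export
ScoreTable <- function(moleculeIds, labels, scores,
                       properties = NULL, source = "constructed") {
    if (is.logical(labels)) labels <- as.integer(labels)
    if (is.numeric(labels)) {
        if (!all(labels %in% c(0, 1))) {
            stop("labels must be binary 0/1 (1 = active, 0 = decoy)")
        }
        labels <- as.integer(labels)
    }
    scores <- .asNamedMatrix(scores, length(moleculeIds), "score")
    if (is.null(properties)) {
        properties <- matrix(numeric(0), nrow = length(moleculeIds), ncol = 0)
    } else {
        properties <- .asNamedMatrix(properties, length(moleculeIds), "property")
    }
    new("ScoreTable", moleculeIds = as.character(moleculeIds), labels = labels,
        scores = scores, properties = properties, source = source)
}

.asNamedMatrix <- function(x, n, what) {
    if (is.data.frame(x)) x <- as.matrix(x)
    if (!is.matrix(x)) x <- matrix(x, nrow = n, dimnames = list(NULL, names(x)))
    storage.mode(x) <- "double"
    if (ncol(x) > 0L && is.null(colnames(x))) {
        stop(what, " columns must be named")
    }
    rownames(x) <- NULL
    x
}

#' Accessors for ScoreTable
#'
#' @param x a \linkS4class{ScoreTable}.
#' @return \code{moleculeIds}: character ids; \code{activityLabels}: 0/1
#'   integer vector; \code{scoreMatrix}: numeric matrix; \code{scoreNames}:
#'   score column names; \code{propertyMatrix}: numeric matrix;
#'   \code{nMolecules}/\code{nActives}: integer counts.
#' @name ScoreTable-accessors
#' @aliases moleculeIds activityLabels scoreMatrix scoreNames propertyMatrix
#'   nMolecules nActives
NULL

#' @rdname ScoreTable-accessors
#' @export
setMethod("moleculeIds", "ScoreTable", function(x) x@moleculeIds)

#' @rdname ScoreTable-accessors
#' @export
setMethod("activityLabels", "ScoreTable", function(x) x@labels)

#' @rdname ScoreTable-accessors
#' @export
setMethod("scoreMatrix", "ScoreTable", function(x) x@scores)

#' @rdname ScoreTable-accessors
#' @export
setMethod("scoreNames", "ScoreTable", function(x) colnames(x@scores))

#' @rdname ScoreTable-accessors
#' @export
setMethod("propertyMatrix", "ScoreTable", function(x) x@properties)

#' @rdname ScoreTable-accessors
#' @export
setMethod("nMolecules", "ScoreTable", function(x) length(x@moleculeIds))

#' @rdname ScoreTable-accessors
#' @export
setMethod("nActives", "ScoreTable", function(x) sum(x@labels == 1L))

setMethod("show", "ScoreTable", function(object) {
    cat("ScoreTable with", nMolecules(object), "molecules (",
        nActives(object), "actives,",
        nMolecules(object) - nActives(object), "decoys )\n")
    cat("  scores    :", paste(scoreNames(object), collapse = ", "), "\n")
    if (ncol(object@properties)) {
        cat("  properties:", paste(colnames(object@properties), collapse = ", "), "\n")
    }
    cat("  source    :", object@source, "\n")
})

#' Subset the rows of a ScoreTable
#'
#' @param x a ScoreTable; @param i row indices.
#' @param i,j,drop standard subscript arguments; only \code{i} is used.
#' @return a ScoreTable with the selected rows.
#' @export
setMethod("[", "ScoreTable", function(x, i, j, ..., drop = FALSE) {
    new("ScoreTable", moleculeIds = x@moleculeIds[i], labels = x@labels[i],
        scores = x@scores[i, , drop = FALSE],
        properties = x@properties[i, , drop = FALSE], source = x@source)
})

#' Read a labeled score table from delimited text
#'
#' Column roles are explicit: the id and label columns are named by the
#' caller, columns listed in \code{propertyCols} (when present in the file)
#' become properties, and every remaining column must be fully numeric and is
#' registered as a score. Missing values are a hard error, never imputed.
#'
#' @param path CSV/TSV file with a header; lines starting with '#' are
#'   ignored. The delimiter is auto-detected from the extension (.tsv/.tab =
#'   tab, otherwise comma) and can be overridden with \code{delim}.
#' @param idCol,labelCol names of the identifier and 0/1 label columns.
#' @param propertyCols column names treated as molecular properties when
#'   present; defaults to molecular weight and heavy-atom count.
#' @param delim optional single-character delimiter override.
#' @return A \linkS4class{ScoreTable}; row order is preserved.
#' @export
readScoreTable <- function(path, idCol = "id", labelCol = "label",
                           propertyCols = c("mw", "heavy_atoms"),
                           delim = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(delim)) {
        delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
    }
    df <- utils::read.table(path, header = TRUE, sep = delim,
                            comment.char = "#", colClasses = "character",
                            check.names = FALSE, quote = "\"",
                            stringsAsFactors = FALSE)
    for (col in c(idCol, labelCol)) {
        if (!col %in% names(df)) stop("column '", col, "' not found in ", path)
    }
    ids <- df[[idCol]]
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) {
        stop("duplicated molecule id(s): ", paste(utils::head(dup, 5L), collapse = ", "))
    }
    labRaw <- tolower(df[[labelCol]])
    labMap <- c("0" = 0L, "1" = 1L, "false" = 0L, "true" = 1L)
    if (!all(labRaw %in% names(labMap))) {
        bad <- which(!labRaw %in% names(labMap))[1L]
        stop("label column '", labelCol, "' must contain only 0/1 or true/false; ",
             "offending row ", bad, " (id ", ids[bad], ")")
    }
    labels <- unname(labMap[labRaw])
    other <- setdiff(names(df), c(idCol, labelCol))
    propNames <- intersect(propertyCols, other)
    scoreNames <- setdiff(other, propNames)
    if (!length(scoreNames)) stop("no score columns found in ", path)
    parseNum <- function(col, role) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(is.na(v) | df[[col]] == "")
        if (length(bad)) {
            stop("non-numeric or missing ", role, " value in column '", col,
                 "', row ", bad[1L], " (id ", ids[bad[1L]], ")")
        }
        v
    }
    scores <- vapply(scoreNames, parseNum, numeric(nrow(df)), role = "score")
    colnames(scores) <- scoreNames
    props <- NULL
    if (length(propNames)) {
        props <- vapply(propNames, parseNum, numeric(nrow(df)), role = "property")
        colnames(props) <- propNames
    }
    ScoreTable(ids, labels, scores, props, source = path)
}

.formatNum <- function(x) {
    # shortest decimal rendering that round-trips doubles exactly
    out <- sprintf("%.17g", x)
    shorter <- sprintf("%.15g", x)
    ok <- as.numeric(shorter) == x
    out[ok] <- shorter[ok]
    mid <- sprintf("%.16g", x)
    ok2 <- !ok & as.numeric(mid) == x
    out[ok2] <- mid[ok2]
    out
}

#' Write a ScoreTable as canonical CSV
#'
#' Canonical column order is id, label, properties, scores, with a
#' full-precision decimal rendering so that write-then-read reproduces every
#' value exactly and re-serialization is byte-identical.
#'
#' @param table a \linkS4class{ScoreTable} with at least one score column.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeScoreTable <- function(table, path) {
    stopifnot(is(table, "ScoreTable"))
    if (ncol(table@scores) == 0L) {
        stop("table has no score columns; nothing to write as scores")
    }
    cols <- c("id", "label", colnames(table@properties), colnames(table@scores))
    body <- cbind(table@moleculeIds, as.character(table@labels))
    if (ncol(table@properties)) {
        body <- cbind(body, apply(table@properties, 2L, .formatNum))
    }
    body <- cbind(body, apply(table@scores, 2L, .formatNum))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c(paste(cols, collapse = ","),
                 apply(body, 1L, paste, collapse = ",")), con)
    invisible(path)
}

#' Normalize a score by a molecular property
#'
#' Docking scores are strongly biased by ligand size; dividing a score by
#' molecular weight (or heavy-atom count) removes the additive-size advantage
#' of large ligands. Appends a new column \code{"<score>_per_<property>"};
#' the original column is untouched.
#'
#' @param table a \linkS4class{ScoreTable}.
#' @param score name of an existing score column.
#' @param property name of an existing, strictly positive property column.
#' @return A new ScoreTable with the derived column appended.
#' @export
normalizeScore <- function(table, score, property) {
    stopifnot(is(table, "ScoreTable"))
    if (!score %in% scoreNames(table)) stop("unknown score column: ", score)
    if (!property %in% colnames(table@properties)) {
        stop("unknown property column: ", property)
    }
    p <- table@properties[, property]
    bad <- which(p <= 0)
    if (length(bad)) {
        stop("property '", property, "' must be strictly positive; offending ",
             "molecule id(s): ",
             paste(utils::head(table@moleculeIds[bad], 5L), collapse = ", "))
    }
    newName <- paste0(score, "_per_", property)
    if (newName %in% scoreNames(table)) {
        stop("score column '", newName, "' already exists")
    }
    scores <- cbind(table@scores, table@scores[, score] / p)
    colnames(scores)[ncol(scores)] <- newName
    new("ScoreTable", moleculeIds = table@moleculeIds, labels = table@labels,
        scores = scores, properties = table@properties, source = table@source)
}
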