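# Amira spatial-graph ASCII I/O.
#
# Dialect (documented byte-exactly, since "spatial graph" names a family of
# layouts): AmiraMesh 3D ASCII 2.0 header; `define VERTEX/EDGE/POINT n`
# counts; a Parameters block carrying ContentType "HxSpatialGraph", units
# and provenance; @-indexed data sections declared as
#   VERTEX { float[3] VertexCoordinates } @1
#   VERTEX { int VertexKind } @2
#   EDGE { int[2] EdgeConnectivity } @3        (0-based vertex indices)
#   EDGE { int NumEdgePoints } @4
#   EDGE { int VesselClass } @5                (0 artery, 1 vein, 2 capillary)
#   POINT { float[3] EdgePointCoordinates } @6 (mm)
#   POINT { float thickness } @7               (radius, um)
# Unknown additional data sections are parsed numerically and preserved in
# the network metadata under `amira_extra`.

AMIRA_CLASSES <- c("artery", "vein", "capillary")
AMIRA_KINDS <- c("inlet-root", "outlet-root", "bifurcation", "terminal",
                 "interior-path-point")

#' Write a vascular network as an Amira spatial-graph ASCII file
#'
#' @param net a [vascular_network]; must be non-empty.
#' @param destination file path.
#' @return invisibly, the destination path.
#' @export
write_amira_spatialgraph <- function(net, destination) {
  stopifnot(inherits(net, "vascular_network"))
  if (n_nodes(net) == 0 || n_segments(net) == 0)
    stop("refusing to write an empty network")
  ids <- net$nodes$id
  npts <- vapply(net$segments, function(s) nrow(s$path), integer(1))
  con <- vapply(net$segments,
                function(s) c(match(s$from, ids), match(s$to, ids)) - 1L,
                integer(2))
  cls <- match(segment_classes(net), AMIRA_CLASSES) - 1L
  kind <- match(net$nodes$kind, AMIRA_KINDS) - 1L
  if (anyNA(cls)) stop("unknown vessel class")
  if (anyNA(kind)) stop("unknown node kind")
  if (anyNA(con)) stop("segment endpoint refers to a missing node")

  num <- function(x) sprintf("%.9g", x)
  lines <- c(
    "# AmiraMesh 3D ASCII 2.0",
    "",
    sprintf("define VERTEX %d", n_nodes(net)),
    sprintf("define EDGE %d", n_segments(net)),
    sprintf("define POINT %d", sum(npts)),
    "",
    "Parameters {",
    "    ContentType \"HxSpatialGraph\",",
    "    Units \"coordinates mm, radius um\",",
    sprintf("    InletVertex %d,",
            if (is.na(net$inlet_id)) -1L else match(net$inlet_id, ids) - 1L),
    sprintf("    OutletVertex %d",
            if (is.na(net$outlet_id)) -1L else match(net$outlet_id, ids) - 1L))
  meta <- net$metadata
  meta <- meta[vapply(meta, function(x) is.atomic(x) && length(x) == 1, logical(1))]
  if (length(meta) > 0) {
    lines[length(lines)] <- paste0(lines[length(lines)], ",")
    ml <- sprintf("    %s \"%s\"%s", names(meta), vapply(meta, as.character, ""),
                  c(rep(",", length(meta) - 1), ""))
    lines <- c(lines, ml)
  }
  lines <- c(lines, "}", "",
    "VERTEX { float[3] VertexCoordinates } @1",
    "VERTEX { int VertexKind } @2",
    "EDGE { int[2] EdgeConnectivity } @3",
    "EDGE { int NumEdgePoints } @4",
    "EDGE { int VesselClass } @5",
    "POINT { float[3] EdgePointCoordinates } @6",
    "POINT { float thickness } @7",
    "",
    "@1",
    paste(num(net$nodes$x), num(net$nodes$y), num(net$nodes$z)),
    "",
    "@2", as.character(kind),
    "",
    "@3", paste(con[1, ], con[2, ]),
    "",
    "@4", as.character(npts),
    "",
    "@5", as.character(cls),
    "",
    "@6",
    unlist(lapply(net$segments, function(s)
      paste(num(s$path[, 1]), num(s$path[, 2]), num(s$path[, 3])))),
    "",
    "@7",
    unlist(lapply(net$segments, function(s) num(s$radius))))
  writeLines(lines, destination)
  invisible(destination)
}

#' Read an Amira spatial-graph ASCII file
#'
#' Counts declared in the header must match the data sections; unknown data
#' fields are preserved numerically in `metadata$amira_extra`.
#'
#' @param source file path.
#' @return a [vascular_network]
#' @export
read_amira_spatialgraph <- function(source) {
  lines <- readLines(source, warn = FALSE)
  if (length(lines) == 0 || !grepl("^#\\s*AmiraMesh .*ASCII", lines[1]))
    stop("malformed header: not an AmiraMesh ASCII file")
  defs <- regmatches(lines, regexec("^define\\s+(\\w+)\\s+(\\d+)", lines))
  defs <- defs[vapply(defs, length, 1L) == 3]
  if (length(defs) == 0) stop("malformed header: no define statements")
  counts <- stats::setNames(as.integer(vapply(defs, `[`, "", 3)),
                            vapply(defs, `[`, "", 2))
  for (k in c("VERTEX", "EDGE", "POINT"))
    if (is.na(counts[k])) stop("malformed header: missing define ", k)

  # declarations:  SECTION { type Name } @k
  decl_re <- "^(\\w+)\\s*\\{\\s*(\\w+(?:\\[\\d+\\])?)\\s+(\\w+)\\s*\\}\\s*@(\\d+)"
  dm <- regmatches(lines, regexec(decl_re, lines))
  decls <- Filter(function(x) length(x) == 5, dm)
  if (length(decls) == 0) stop("malformed header: no data declarations")
  decl <- do.call(rbind, lapply(decls, function(x)
    data.frame(section = x[2], type = x[3], name = x[4],
               mark = as.integer(x[5]), stringsAsFactors = FALSE)))
  decl$width <- rep(1L, nrow(decl))
  wide <- grepl("\\[", decl$type)
  decl$width[wide] <- as.integer(sub(".*\\[(\\d+)\\].*", "\\1",
                                     decl$type[wide]))

  # data blocks
  at <- grep("^@\\d+\\s*$", lines)
  blocks <- list()
  for (i in seq_along(at)) {
    k <- as.integer(sub("@", "", trimws(lines[at[i]])))
    end <- if (i < length(at)) at[i + 1] - 1 else length(lines)
    body <- lines[(at[i] + 1):end]
    body <- body[nzchar(trimws(body))]
    vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
    if (anyNA(vals)) stop("non-numeric payload in data section @", k)
    blocks[[as.character(k)]] <- vals
  }

  get_block <- function(name, required = TRUE) {
    row <- decl[decl$name == name, , drop = FALSE]
    if (nrow(row) == 0) {
      if (required) stop("malformed header: missing declaration ", name)
      return(NULL)
    }
    vals <- blocks[[as.character(row$mark[1])]]
    if (is.null(vals)) stop("missing data section for ", name)
    expected <- counts[row$section[1]] * row$width[1]
    if (length(vals) != expected)
      stop("count mismatch in ", name, ": header declares ", expected,
           " values, body has ", length(vals))
    if (row$width[1] > 1)
      matrix(vals, ncol = row$width[1], byrow = TRUE)
    else vals
  }

  coords <- get_block("VertexCoordinates")
  conn <- get_block("EdgeConnectivity")
  npts <- as.integer(get_block("NumEdgePoints"))
  pts <- get_block("EdgePointCoordinates")
  thick <- get_block("thickness")
  vclass <- get_block("VesselClass", required = FALSE)
  vkind <- get_block("VertexKind", required = FALSE)
  if (sum(npts) != counts["POINT"])
    stop("count mismatch: NumEdgePoints total differs from POINT count")
  if (counts["EDGE"] > 0 && is.null(dim(conn))) conn <- matrix(conn, ncol = 2)

  # parameters: inlet/outlet and free-form provenance
  inlet <- outlet <- NA_integer_
  meta <- list()
  pstart <- grep("^Parameters\\s*\\{", lines)
  if (length(pstart) == 1) {
    pend <- pstart
    depth <- 0
    for (j in pstart:length(lines)) {
      depth <- depth + lengths(regmatches(lines[j], gregexpr("\\{", lines[j]))) -
        lengths(regmatches(lines[j], gregexpr("\\}", lines[j])))
      if (depth == 0) { pend <- j; break }
    }
    for (pl in lines[(pstart + 1):(pend - 1)]) {
      m <- regmatches(pl, regexec('^\\s*(\\w+)\\s+"?([^",]*)"?,?\\s*$', pl))[[1]]
      if (length(m) == 3) {
        key <- m[2]; val <- m[3]
        if (key == "InletVertex") inlet <- as.integer(val)
        else if (key == "OutletVertex") outlet <- as.integer(val)
        else meta[[key]] <- val
      }
    }
  }

  kinds <- if (!is.null(vkind)) AMIRA_KINDS[as.integer(vkind) + 1L]
           else rep("bifurcation", counts["VERTEX"])
  nodes <- data.frame(id = seq_len(counts["VERTEX"]),
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      kind = kinds, stringsAsFactors = FALSE)
  classes <- if (!is.null(vclass)) AMIRA_CLASSES[as.integer(vclass) + 1L]
             else rep("artery", counts["EDGE"])
  offs <- c(0L, cumsum(npts))
  segments <- lapply(seq_len(counts["EDGE"]), function(i) {
    idx <- (offs[i] + 1):offs[i + 1]
    list(id = i, from = conn[i, 1] + 1L, to = conn[i, 2] + 1L,
         path = pts[idx, , drop = FALSE], radius = thick[idx],
         class = classes[i])
  })

  known <- c("VertexCoordinates", "VertexKind", "EdgeConnectivity",
             "NumEdgePoints", "VesselClass", "EdgePointCoordinates",
             "thickness")
  extra <- decl[!decl$name %in% known, , drop = FALSE]
  if (nrow(extra) > 0) {
    meta$amira_extra <- stats::setNames(
      lapply(seq_len(nrow(extra)), function(i)
        blocks[[as.character(extra$mark[i])]]),
      extra$name)
  }
  vascular_network(nodes, segments,
                   inlet_id = if (!is.na(inlet) && inlet >= 0) inlet + 1L else NA_integer_,
                   outlet_id = if (!is.na(outlet) && outlet >= 0) outlet + 1L else NA_integer_,
                   metadata = meta)
}
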