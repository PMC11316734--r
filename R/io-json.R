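# JSON network dialect, versioned. Schema (version 1):
# {
#   "format": "retinavasc-network", "version": 1,
#   "units": {"coordinates": "mm", "radius": "um"},
#   "inlet_id": int|null, "outlet_id": int|null,
#   "nodes": [{"id": int, "x": num, "y": num, "z": num, "kind": str}, ...],
#   "segments": [{"id": int, "from": int, "to": int, "class": str,
#                 "path": [[x,y,z], ...], "radius": [num, ...]}, ...],
#   "metadata": {...}
# }

#' Write a vascular network to the versioned JSON dialect
#' @param net a [vascular_network]
#' @param destination file path
#' @export
write_network_json <- function(net, destination) {
  stopifnot(inherits(net, "vascular_network"))
  obj <- list(
    format = "retinavasc-network", version = 1L,
    units = list(coordinates = "mm", radius = "um"),
    inlet_id = if (is.na(net$inlet_id)) NULL else net$inlet_id,
    outlet_id = if (is.na(net$outlet_id)) NULL else net$outlet_id,
    nodes = net$nodes,
    segments = lapply(net$segments, function(s)
      list(id = s$id, from = s$from, to = s$to, class = s$class,
           path = unname(s$path), radius = s$radius)),
    metadata = net$metadata)
  jsonlite::write_json(obj, destination, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(destination)
}

#' Read a vascular network from the JSON dialect
#' @param source file path
#' @export
read_network_json <- function(source) {
  obj <- jsonlite::read_json(source, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE, simplifyMatrix = TRUE)
  if (!identical(obj$format, "retinavasc-network"))
    stop("not a retinavasc network JSON file")
  if (!identical(as.integer(obj$version), 1L))
    stop("unsupported network JSON version: ", obj$version)
  segs <- obj$segments
  if (is.data.frame(segs)) {
    segs <- lapply(seq_len(nrow(segs)), function(i) {
      list(id = segs$id[i], from = segs$from[i], to = segs$to[i],
           class = segs$class[i], path = segs$path[[i]],
           radius = segs$radius[[i]])
    })
  }
  vascular_network(obj$nodes, segs,
                   inlet_id = obj$inlet_id %||% NA_integer_,
                   outlet_id = obj$outlet_id %||% NA_integer_,
                   metadata = as.list(obj$metadata))
}
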