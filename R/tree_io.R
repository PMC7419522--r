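# Tree file I/O. CSV dialect: header id,parent_id,x0,y0,z0,x1,y1,z1,diameter_m
# with parent_id empty for the root; lengths are derived from endpoints.
# JSON dialect: {"segments": [...same fields...], "metadata": {"gravity": [..]}}.
# File-supplied ids are remapped to breadth-first states; the lookup is kept
# in attr(tree, "id_map").

#' Read an airway tree from CSV or JSON
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format "csv" or "json".
#' @return An [airway_tree()].
#' @export
read_airway_tree <- function(path,
                             format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    df <- as.data.frame(obj$segments)
    gravity <- c(0, 0, -1)
    if (!is.null(obj$metadata$gravity)) gravity <- as.numeric(obj$metadata$gravity)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    gravity <- c(0, 0, -1)
  }
  req <- c("id", "parent_id", "x0", "y0", "z0", "x1", "y1", "z1", "diameter_m")
  if (!all(req %in% names(df))) {
    stop("tree file must contain columns ", paste(req, collapse = ","))
  }
  parent_id <- df$parent_id
  if (is.character(parent_id)) parent_id[parent_id == ""] <- NA
  parent <- match(parent_id, df$id)
  if (any(is.na(parent) & !is.na(parent_id))) stop("parent_id not found among ids")
  seg <- data.frame(id = df$id, parent = parent,
                    x0 = df$x0, y0 = df$y0, z0 = df$z0,
                    x1 = df$x1, y1 = df$y1, z1 = df$z1,
                    diameter = df$diameter_m, stringsAsFactors = FALSE)
  airway_tree(seg, gravity = gravity)
}

#' Write an airway tree to CSV or JSON
#'
#' @param tree An [airway_tree()].
#' @param path Output path.
#' @param format "csv" or "json" (inferred from the extension by default).
#' @return `path`, invisibly.
#' @export
write_airway_tree <- function(tree, path,
                              format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- data.frame(id = tree$state,
                   parent_id = tree$parent,
                   x0 = tree$x0, y0 = tree$y0, z0 = tree$z0,
                   x1 = tree$x1, y1 = tree$y1, z1 = tree$z1,
                   diameter_m = tree$diameter)
  if (format == "json") {
    obj <- list(segments = df,
                metadata = list(gravity = attr(tree, "gravity")))
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         na = "null")
  } else {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' The printed single-tube benchmark geometry
#'
#' The one airway dimension pair used for the single-tube tradeoff
#' analyses: a third-generation-bronchus-sized tube of length 6.3 cm and
#' diameter 1.35 cm, horizontal by default.
#'
#' @param angle Gravity angle in radians (default horizontal).
#' @return A [tube()].
#' @export
benchmark_tube <- function(angle = 0) {
  tube(length = 0.063, diameter = 0.0135, angle = angle)
}
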