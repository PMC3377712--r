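#' Write placements to a jplace file
#'
#' Serialises an attachment table and its reference tree in the jplace
#' interchange format (version 3): the tree is embedded as newick with
#' `{n}` edge numbers, and each read contributes one placement record with
#' fields `edge_num`, `like_weight_ratio`, `distal_length`,
#' `pendant_length`.
#'
#' @param placements attachment tibble (`read_id`, `edge_id`,
#'   `distal_length`, `pendant_length`, `posterior`; an optional `sample`
#'   column is stored in the name multiplicity field).
#' @param tree the placement tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jplace <- function(placements, tree, path) {
  tree <- as_placement_tree(tree)
  et <- edge_table(tree)
  bad <- setdiff(placements$edge_id, et$edge_id)
  if (length(bad)) {
    stop("unknown edge_id in placements: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  by_read <- split(placements, placements$read_id)
  recs <- lapply(names(by_read), function(id) {
    d <- by_read[[id]]
    list(
      p = lapply(seq_len(nrow(d)), function(i) {
        list(d$edge_id[i], d$posterior[i], d$distal_length[i], d$pendant_length[i])
      }),
      nm = list(list(id, 1L))
    )
  })
  obj <- list(
    version = 3L,
    tree = write_edge_newick(tree),
    fields = c("edge_num", "like_weight_ratio", "distal_length", "pendant_length"),
    placements = recs,
    metadata = list(invocation = "placemass::write_jplace")
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read a jplace file
#'
#' Accepts any field order declared in the file's `fields` array; the
#' `like_weight_ratio` values are renormalised to sum to 1 per read (files
#' sometimes truncate mass).
#'
#' @param path jplace file.
#' @return list with `placements` (tibble: `read_id`, `edge_id`,
#'   `distal_length`, `pendant_length`, `posterior`) and `tree`.
#' @export
read_jplace <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("malformed jplace JSON: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(obj$tree)) stop("jplace file has no tree string", call. = FALSE)
  if (is.null(obj$fields)) stop("jplace file has no fields array", call. = FALSE)
  fields <- unlist(obj$fields)
  need <- c("edge_num", "like_weight_ratio", "distal_length", "pendant_length")
  if (!all(need %in% fields)) {
    stop("jplace fields must include: ", paste(need, collapse = ", "), call. = FALSE)
  }
  parsed <- read_edge_newick(obj$tree)
  edge_of <- stats::setNames(parsed$edge_map$edge_id, parsed$edge_map$edge_num)

  rows <- lapply(obj$placements, function(rec) {
    ids <- if (!is.null(rec$nm)) {
      vapply(rec$nm, function(x) as.character(x[[1]]), character(1))
    } else if (!is.null(rec$n)) {
      unlist(rec$n)
    } else {
      stop("placement record without read names", call. = FALSE)
    }
    p <- do.call(rbind, lapply(rec$p, function(x) as.numeric(unlist(x))))
    colnames(p) <- fields
    lapply(ids, function(id) {
      tibble::tibble(
        read_id = id,
        edge_num = as.integer(p[, "edge_num"]),
        distal_length = p[, "distal_length"],
        pendant_length = p[, "pendant_length"],
        posterior = p[, "like_weight_ratio"]
      )
    })
  })
  out <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
  eid <- edge_of[as.character(out$edge_num)]
  if (anyNA(eid)) stop("placement references an edge_num absent from the tree",
                       call. = FALSE)
  out$edge_id <- unname(eid)
  out <- dplyr::group_by(out, .data$read_id)
  out <- dplyr::mutate(out, posterior = .data$posterior / sum(.data$posterior))
  out <- dplyr::ungroup(out)
  list(
    placements = out[, c("read_id", "edge_id", "distal_length",
                         "pendant_length", "posterior")],
    tree = parsed$tree
  )
}
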