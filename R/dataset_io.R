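# ---- manifests, splitting, config IO ----------------------------------

#' Split specification
#'
#' @param fractions `c(train, val, test)` positive fractions summing to 1
#'   (default 0.8/0.1/0.1).
#' @param rng_seed integer seed controlling the (order-invariant) shuffle.
#' @return a `split_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.8, val = 0.1, test = 0.1),
                       rng_seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three positive numbers summing to 1")
  names(fractions) <- c("train", "val", "test")
  structure(list(fractions = fractions, rng_seed = as.integer(rng_seed)),
            class = "split_spec")
}

# Largest-remainder apportionment of `n` items over the fractions.
.apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Leakage-free stratified split
#'
#' Assigns train/val/test tags stratified by class while keeping every
#' leaf instance (all renders sharing an `instance_id`) inside a single
#' subset, so no physical leaf leaks across subsets. Instance groups are
#' sorted before the seeded shuffle, making the split invariant to input
#' record order. Subset sizes per class follow largest-remainder
#' apportionment over the instance groups, so per-class fractions are
#' within one group of the request.
#'
#' @param records list of `leaf_record`s (each with `label` and
#'   `instance_id`).
#' @param spec a [split_spec()].
#' @return the records with `split` tags filled in, in the input order.
#' @export
stratified_group_split <- function(records, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  labels <- vapply(records, `[[`, "", "label")
  inst <- vapply(records, `[[`, "", "instance_id")
  if (any(!nzchar(labels)) || any(!nzchar(inst)))
    stop("every record needs a label and an instance_id")
  classes <- sort(unique(labels))
  seeds <- with_seed(spec$rng_seed, sample.int(1e9, length(classes)))
  assignment <- character(length(records))
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    in_cls <- which(labels == cls)
    groups <- sort(unique(inst[in_cls]))
    if (length(groups) < 3L)
      stop("class '", cls, "' has fewer than 3 instance groups; ",
           "cannot populate train/val/test")
    perm <- with_seed(seeds[ci], sample(groups))
    sizes <- .apportion(length(groups), spec$fractions)
    # guarantee every subset is populated
    for (j in which(sizes == 0)) {
      donor <- which.max(sizes)
      sizes[j] <- 1; sizes[donor] <- sizes[donor] - 1
    }
    tags <- rep(names(spec$fractions), times = sizes)
    g2s <- stats::setNames(tags, perm)
    assignment[in_cls] <- g2s[inst[in_cls]]
  }
  for (i in seq_along(records)) records[[i]]$split <- assignment[i]
  records
}

#' Write a dataset manifest
#'
#' @param records list of `leaf_record`s that were written to disk (the
#'   manifest stores paths relative to its own directory).
#' @param path CSV file path.
#' @seealso [write_leaf_dataset()] which writes images and manifest in one
#'   call.
#' @export
write_manifest <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(path = file.path(r$label, paste0(r$instance_id, "_", r$render, ".png")),
               mask_path = file.path("masks", r$label,
                                     paste0(r$instance_id, "_", r$render, ".png")),
               label = r$label, instance_id = r$instance_id, split = r$split,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Load a dataset manifest
#'
#' Reads a CSV with columns path, mask_path, label, instance_id and
#' optional split, resolves paths relative to the manifest, validates
#' that every referenced image exists and decodes, and returns
#' `leaf_record`s (images in `[0,1]`). `leaf_mask_truth` is not stored on
#' disk and is left `NULL`; recompute it with [leaf_mask()] if needed.
#'
#' @param path manifest CSV.
#' @param validate decode every image (default) or trust the listing.
#' @return list of `leaf_record`s.
#' @export
load_manifest <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "mask_path", "label", "instance_id")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  root <- dirname(path)
  if (!"split" %in% names(df)) df$split <- "unassigned"
  lapply(seq_len(nrow(df)), function(i) {
    f <- file.path(root, df$path[i])
    mf <- file.path(root, df$mask_path[i])
    if (!file.exists(f)) stop("manifest row ", i, ": missing image file ", df$path[i])
    if (!file.exists(mf)) stop("manifest row ", i, ": missing mask file ", df$mask_path[i])
    rgb <- NULL; vein <- NULL
    if (validate) {
      rgb <- tryCatch(png::readPNG(f), error = function(e)
        stop("manifest row ", i, ": unreadable image ", df$path[i]))
      if (length(dim(rgb)) == 3 && dim(rgb)[3] == 4) rgb <- rgb[, , 1:3]
      m <- tryCatch(png::readPNG(mf), error = function(e)
        stop("manifest row ", i, ": unreadable mask ", df$mask_path[i]))
      if (length(dim(m)) == 3) m <- m[, , 1]
      vein <- (m > 0.5) * 1
    }
    render <- sub(".*_([0-9]+)\\.png$", "\\1", df$path[i])
    structure(list(rgb = rgb, vein_truth = vein, leaf_mask_truth = NULL,
                   label = df$label[i], instance_id = df$instance_id[i],
                   render = suppressWarnings(as.integer(render)),
                   split = df$split[i], path = f, mask_path = mf),
              class = "leaf_record")
  })
}

#' Read / write a flat YAML pipeline configuration
#'
#' The YAML mirrors [vein_pipeline_config()] field names; structuring
#' elements are written as `shape:size` strings.
#'
#' @param path YAML file.
#' @return a `vein_pipeline_config`.
#' @export
read_vein_config <- function(path) {
  y <- yaml::read_yaml(path)
  se <- function(s) {
    parts <- strsplit(s, ":")[[1]]
    struct_elem(parts[1], as.integer(parts[2]))
  }
  for (nm in c("opening_se", "closing_se"))
    if (!is.null(y[[nm]]) && is.character(y[[nm]])) y[[nm]] <- se(y[[nm]])
  do.call(vein_pipeline_config, y)
}
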