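# Dataset I/O: lossless PNG slices plus a diffable CSV manifest
# (case_id, label, slice_index, path, is_lesion_cut), with image paths
# relative to the manifest's directory so runs are relocatable.

manifest_columns <- c("case_id", "label", "slice_index", "path",
                      "is_lesion_cut")

cases_to_manifest <- function(cases, path_fun) {
  rows <- lapply(cases, function(cs) {
    data.frame(case_id = cs$case_id, label = cs$label,
               slice_index = vapply(cs$slices, `[[`, integer(1),
                                    "slice_index"),
               path = vapply(cs$slices, function(s)
                 path_fun(cs$case_id, s$slice_index), character(1)),
               is_lesion_cut = vapply(cs$slices, `[[`, logical(1),
                                      "is_lesion_cut"))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- as.data.frame(setNames(
    list(character(0), character(0), integer(0), character(0), logical(0)),
    manifest_columns))
  df[order(df$case_id, df$slice_index), , drop = FALSE]
}

#' Write a case manifest CSV
#'
#' Fixed header `case_id,label,slice_index,path,is_lesion_cut`; rows sorted
#' by `(case_id, slice_index)`; byte-stable for identical input.
#'
#' @param cases list of `oct_case`.
#' @param path output CSV path.
#' @return the manifest data.frame, invisibly.
#' @export
write_manifest <- function(cases, path) {
  df <- cases_to_manifest(cases, function(id, idx)
    file.path(id, sprintf("%02d.png", idx)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write a synthetic dataset to disk
#'
#' One PNG per slice under `out/<case_id>/<slice_index>.png` plus
#' `manifest.csv` at the top level.
#'
#' @param cases list of `oct_case`.
#' @param out output directory (created if needed).
#' @return path of the manifest, invisibly.
#' @export
write_dataset <- function(cases, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (cs in cases) {
    d <- file.path(out, cs$case_id)
    dir.create(d, showWarnings = FALSE)
    for (s in cs$slices)
      png::writePNG(s$pixels / 255,
                    file.path(d, sprintf("%02d.png", s$slice_index)))
  }
  mpath <- file.path(out, "manifest.csv")
  write_manifest(cases, mpath)
  invisible(mpath)
}

#' Read and validate a case manifest
#'
#' Checks the full contract — known labels, unique
#' `(case_id, slice_index)`, gap-free 0-based slice indices, normal cases
#' free of lesion flags, image files present — and reports the first
#' violating row in each error.
#'
#' @param path manifest CSV path; image paths are resolved relative to its
#'   directory.
#' @param load_images read the PNGs and return full `oct_case` objects
#'   (otherwise `cases` is `NULL`).
#' @return list with `manifest` (data.frame) and `cases`.
#' @export
read_manifest <- function(path, load_images = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(manifest_columns %in% names(df)))
    stop("manifest must have columns ",
         paste(manifest_columns, collapse = ","))
  root <- dirname(path)
  bad <- which(!df$label %in% CSC_LABELS)
  if (length(bad))
    stop("row ", bad[1], ": unknown label '", df$label[bad[1]], "'")
  key <- paste(df$case_id, df$slice_index)
  if (anyDuplicated(key))
    stop("row ", which(duplicated(key))[1], ": duplicate slice ",
         key[which(duplicated(key))[1]])
  for (id in unique(df$case_id)) {
    sub <- df[df$case_id == id, ]
    idx <- sort(sub$slice_index)
    if (!identical(idx, seqalong0(idx)))
      stop("case ", id, ": slice indices have gaps (found ",
           paste(idx, collapse = ","), ")")
    if (sub$label[1] == "normal" && any(sub$is_lesion_cut))
      stop("case ", id, ": normal case flagged is_lesion_cut=TRUE")
    if (sub$label[1] != "normal" && !any(sub$is_lesion_cut))
      stop("case ", id, ": CSC case with zero lesion cuts")
  }
  cases <- NULL
  if (load_images) {
    missing <- !file.exists(file.path(root, df$path))
    if (any(missing))
      stop("row ", which(missing)[1], ": missing image file ",
           df$path[which(missing)[1]])
    cases <- lapply(unique(df$case_id), function(id) {
      sub <- df[df$case_id == id, ]
      sub <- sub[order(sub$slice_index), ]
      slices <- lapply(seq_len(nrow(sub)), function(i) {
        px <- png::readPNG(file.path(root, sub$path[i]))
        if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
        px <- px[, , 1:3, drop = FALSE]
        storage.mode(px) <- "double"
        pxi <- array(as.integer(round(px * 255)), dim(px))
        new_slice_image(pxi, sub$slice_index[i], sub$is_lesion_cut[i])
      })
      structure(list(case_id = id, label = sub$label[1], slices = slices),
                class = "oct_case")
    })
  }
  list(manifest = df, cases = cases)
}

seqalong0 <- function(x) seq.int(0L, length.out = length(x))

#' Read a run configuration (YAML or JSON)
#'
#' Maps a config file onto the pipeline's parameter objects. Recognised
#' top-level keys: `preprocess`, `augment`, `sip`, `hyper`, `fd`, `synth`,
#' `folds` (with `k` and `seed`); unknown keys are rejected.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return list with `config` (a [csc_config()]), `synth`
#'   (a [synth_params()] or `NULL`), `k` and `seed`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- c("preprocess", "augment", "sip", "hyper", "fd", "synth", "folds")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ","))
  build <- function(fun, args) do.call(fun, as.list(args %||% list()))
  list(config = csc_config(
         sip = build(sip_spec, raw$sip),
         fd = build(fd_spec, raw$fd),
         hyper = build(train_hyper, raw$hyper),
         p = build(preprocess_params, raw$preprocess),
         a = build(augment_params, raw$augment)),
       synth = if (!is.null(raw$synth)) build(synth_params, raw$synth),
       k = raw$folds$k %||% 5L,
       seed = raw$folds$seed %||% 1L)
}
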