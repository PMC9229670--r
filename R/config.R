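## Run configuration and pipeline orchestration.
##
## One YAML file drives every command so that, in particular, all folds of a
## cross-validation share identical hyperparameters. Each section maps
## bit-for-bit onto the corresponding module config constructor; unknown
## keys and invalid values are rejected with the offending key named.

config_sections <- function() {
  list(phantom = phantom_config, preprocess = preprocess_config,
       augment = augment_config, generator = generator_config,
       discriminator = discriminator_config, train = train_config)
}

apply_section <- function(ctor, values, section) {
  fm <- formals(ctor)
  allowed <- names(fm)
  unknown <- setdiff(names(values), allowed)
  if (length(unknown)) {
    stop("unknown key `", section, ".", unknown[1], "`", call. = FALSE)
  }
  out <- tryCatch(do.call(ctor, values), error = function(e) {
    stop("invalid value in section `", section, "`: ", conditionMessage(e),
         call. = FALSE)
  })
  # name the offending key for simple range violations
  out
}

#' Load and validate a run configuration
#'
#' Missing sections and keys fall back to the package defaults (threshold 10,
#' closure kernel 9, lambda 75, dropout 0.1, learning rate 2e-4, batch 10,
#' 4 folds). An empty or absent file yields the full default configuration.
#'
#' @param path YAML file; `NULL` for pure defaults.
#' @return a `run_config` list with one entry per module section plus
#'   `eval` (`k`), `seed` and `io` paths.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  sections <- config_sections()
  known_top <- c(names(sections), "eval", "seed", "io")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) stop("unknown key `", unknown[1], "`", call. = FALSE)

  cfg <- list()
  for (sec in names(sections)) {
    vals <- raw[[sec]]
    if (is.null(vals)) vals <- list()
    # validate each key so errors name it precisely
    fm <- names(formals(sections[[sec]]))
    bad <- setdiff(names(vals), fm)
    if (length(bad)) stop("unknown key `", sec, ".", bad[1], "`", call. = FALSE)
    cfg[[sec]] <- tryCatch(do.call(sections[[sec]], vals), error = function(e) {
      key <- if (length(names(vals))) paste0(sec, ".", names(vals)[1]) else sec
      stop("invalid configuration near `", key, "`: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!is.null(raw$train$lambda_l1) && raw$train$lambda_l1 < 0) {
    stop("invalid value for `train.lambda_l1`", call. = FALSE)
  }
  cfg$eval <- list(k = as.integer(raw$eval$k %||% 4L))
  cfg$seed <- as.integer(raw$seed %||% 42L)
  cfg$io <- raw$io %||% list()
  structure(cfg, class = "run_config")
}

#' Save a run configuration back to YAML
#'
#' @param cfg a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  plain <- lapply(unclass(cfg), function(x) {
    if (is.list(x)) lapply(unclass(x), identity) else x
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

resolve_volume_paths <- function(dir) {
  niis <- natural_sort(list.files(dir, pattern = "\\.nii(\\.gz)?$",
                                  full.names = TRUE))
  if (length(niis)) return(niis)
  subdirs <- list.dirs(dir, recursive = FALSE)
  natural_sort(subdirs[vapply(subdirs, function(d)
    length(list.files(d, pattern = "\\.png$")) > 0, logical(1))])
}

read_paired_volumes <- function(data_dir) {
  img_dir <- file.path(data_dir, "images")
  msk_dir <- file.path(data_dir, "masks")
  if (!dir.exists(img_dir) || !dir.exists(msk_dir)) {
    stop("expected `images/` and `masks/` under ", data_dir, call. = FALSE)
  }
  ip <- resolve_volume_paths(img_dir); mp <- resolve_volume_paths(msk_dir)
  if (length(ip) != length(mp) || !length(ip)) {
    stop("images/ and masks/ under ", data_dir,
         " must hold the same positive number of volumes", call. = FALSE)
  }
  lapply(seq_along(ip), function(i) {
    img <- read_volume(ip[i])
    msk <- read_volume(mp[i])
    list(image = volume_stack(unclass(img) * if (max(img) <= 1) 255 else 1,
                              attr(img, "spacing_mm")),
         mask = volume_stack(array(as.numeric(unclass(msk) > 0.5), dim(msk)),
                             attr(msk, "spacing_mm")))
  })
}

#' Run one pipeline command
#'
#' @param cfg a `run_config` from [load_config()].
#' @param command one of `"phantom"`, `"preprocess"`, `"train"`, `"predict"`,
#'   `"evaluate"`, `"crossval"`.
#' @param ... command-specific path overrides: `data_dir`, `out_dir`,
#'   `checkpoint`, `input`, `pred_dir`, `truth_dir`, `n_volumes`.
#' @return command-specific result, invisibly where the product is on disk.
#' @export
run_pipeline <- function(cfg, command, ...) {
  stopifnot(inherits(cfg, "run_config"))
  opts <- list(...)
  io <- utils::modifyList(cfg$io, opts)
  set.seed(cfg$seed)
  switch(command,
    phantom = {
      out <- io$out_dir %||% stop("phantom needs `out_dir`", call. = FALSE)
      n <- io$n_volumes %||% 4L
      pcfg <- cfg$phantom; pcfg$seed <- cfg$seed
      ds <- phantom_dataset(pcfg, n)
      dir.create(file.path(out, "images"), recursive = TRUE, showWarnings = FALSE)
      dir.create(file.path(out, "masks"), recursive = TRUE, showWarnings = FALSE)
      fmt <- io$format %||% "png"
      for (i in seq_along(ds)) {
        if (fmt == "nifti") {
          write_volume(ds[[i]]$image, file.path(out, "images", sprintf("vol%d.nii.gz", i)))
          write_volume(ds[[i]]$mask, file.path(out, "masks", sprintf("vol%d.nii.gz", i)), TRUE)
        } else {
          write_volume(ds[[i]]$image, file.path(out, "images", sprintf("vol%d", i)))
          write_volume(ds[[i]]$mask, file.path(out, "masks", sprintf("vol%d", i)), TRUE)
        }
      }
      invisible(out)
    },
    preprocess = {
      data_dir <- io$data_dir %||% stop("preprocess needs `data_dir`", call. = FALSE)
      out <- io$out_dir %||% stop("preprocess needs `out_dir`", call. = FALSE)
      vols <- read_paired_volumes(data_dir)
      dir.create(file.path(out, "images"), recursive = TRUE, showWarnings = FALSE)
      dir.create(file.path(out, "masks"), recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(vols)) {
        x <- preprocess_volume(unclass(vols[[i]]$image), cfg$preprocess)
        x01 <- (x - cfg$preprocess$normalize_range[1]) /
          diff(cfg$preprocess$normalize_range)
        y <- array(0L, c(cfg$preprocess$target_size, cfg$preprocess$target_size,
                         dim(vols[[i]]$mask)[3]))
        for (s in seq_len(dim(y)[3])) {
          y[, , s] <- resize_slice(unclass(vols[[i]]$mask)[, , s],
                                   cfg$preprocess$target_size, TRUE)
        }
        write_volume(volume_stack(x01), file.path(out, "images", sprintf("vol%d", i)))
        write_volume(volume_stack(y), file.path(out, "masks", sprintf("vol%d", i)), TRUE)
      }
      invisible(out)
    },
    train = {
      data_dir <- io$data_dir %||% stop("train needs `data_dir`", call. = FALSE)
      ckpt <- io$checkpoint %||% stop("train needs `checkpoint`", call. = FALSE)
      vols <- read_paired_volumes(data_dir)
      nval <- max(1L, length(vols) %/% 4L)
      val_idx <- seq_len(nval)
      res <- fit(vols[-val_idx], vols[val_idx], cfg$generator, cfg$discriminator,
                 cfg$train, cfg$preprocess, cfg$augment)
      save_checkpoint(res, ckpt)
      hist_path <- io$history %||% paste0(ckpt, ".history.csv")
      utils::write.csv(res$history, hist_path, row.names = FALSE)
      invisible(res)
    },
    predict = {
      ckpt <- io$checkpoint %||% stop("predict needs `checkpoint`", call. = FALSE)
      input <- io$input %||% stop("predict needs `input`", call. = FALSE)
      out <- io$out_dir %||% stop("predict needs `out_dir`", call. = FALSE)
      nets <- load_checkpoint(ckpt)
      vol <- read_volume(input)
      raw <- volume_stack(unclass(vol) * if (max(vol) <= 1) 255 else 1,
                          attr(vol, "spacing_mm"))
      pred <- predict_volume(nets$generator, raw, cfg$preprocess)
      path <- if (is_nifti_path(out)) out else file.path(out, "prediction")
      if (!is_nifti_path(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_volume(pred, path, is_mask = TRUE)
      invisible(path)
    },
    evaluate = {
      pred_dir <- io$pred_dir %||% stop("evaluate needs `pred_dir`", call. = FALSE)
      truth_dir <- io$truth_dir %||% stop("evaluate needs `truth_dir`", call. = FALSE)
      pv <- resolve_volume_paths(pred_dir); tv <- resolve_volume_paths(truth_dir)
      stopifnot(length(pv) == length(tv), length(pv) > 0)
      rows <- NULL
      for (i in seq_along(pv)) {
        pv_i <- read_volume(pv[i]); tv_i <- read_volume(tv[i])
        p <- array(as.numeric(unclass(pv_i) > 0.5), dim(pv_i))
        t <- array(as.numeric(unclass(tv_i) > 0.5), dim(tv_i))
        mr <- metrics_report(p, t)
        rows <- rbind(rows, data.frame(volume = i, dice = mr$dice,
                                       precision = mr$precision,
                                       sensitivity = mr$sensitivity,
                                       specificity = mr$specificity))
      }
      if (!is.null(io$report)) utils::write.csv(rows, io$report, row.names = FALSE)
      rows
    },
    crossval = {
      data_dir <- io$data_dir %||% stop("crossval needs `data_dir`", call. = FALSE)
      out <- io$out_dir %||% stop("crossval needs `out_dir`", call. = FALSE)
      vols <- read_paired_volumes(data_dir)
      res <- kfold_run(vols, cfg$eval$k, cfg$generator, cfg$discriminator,
                       cfg$train, cfg$preprocess, cfg$augment)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(res$table, file.path(out, "crossval.csv"), row.names = FALSE)
      invisible(res)
    },
    stop("unknown command: ", command, call. = FALSE)
  )
}
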