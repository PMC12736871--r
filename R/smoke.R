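# Desk-scale end-to-end harness: train the tiny-encoder FADeepLabV3 on a
# small synthetic phantom cohort and verify that segmentation quality rises
# well above its initialisation. Also the entry point used by the
# reproduction script.

#' Generate the desk-scale phantom cohort
#'
#' 64 lesion-bearing phantoms at 64 x 64 (40 benign, 24 malignant,
#' mirroring the roughly 2:1 benign:malignant imbalance of clinical
#' breast-ultrasound corpora), stratified 48/8/8 into train/val/test.
#'
#' @param seed integer seed.
#' @param n_benign,n_malignant per-class counts.
#' @param image_size phantom side in pixels.
#' @return list with `train`, `val`, `test` sample lists.
#' @export
smoke_phantom_cohort <- function(seed = 1L, n_benign = 40L, n_malignant = 24L,
                                 image_size = 64L) {
  classes <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  samples <- lapply(seq_along(classes), function(i) {
    generate_phantom(phantom_config(image_size = c(image_size, image_size),
                                    class = classes[i],
                                    seed = sub_seed(seed, paste0("smoke-", i))))
  })
  sp <- stratified_split(classes, ratios = c(0.75, 0.125, 0.125), seed = seed)
  list(train = samples[sp$assignment == "train"],
       val = samples[sp$assignment == "val"],
       test = samples[sp$assignment == "test"])
}

#' Desk-scale segmentation training run
#'
#' Trains a tiny-encoder FADeepLabV3 (output stride 8) on the
#' [smoke_phantom_cohort()] with Dice loss for up to `max_epochs` epochs on
#' one CPU, and reports validation mean Dice before and after training.
#'
#' @param seed integer run seed.
#' @param max_epochs epoch cap (default 30).
#' @param verbose print per-epoch losses.
#' @return list with `fit`, `init_dice`, `final_dice`, `improvement` and
#'   `val_metrics`.
#' @export
smoke_train_segmentation <- function(seed = 1L, max_epochs = 30L, verbose = FALSE) {
  data <- smoke_phantom_cohort(seed)
  net <- build_segmenter(seg_config("fadeeplabv3", encoder_kind = "tiny",
                                    output_stride = 8L, seed = seed))
  cfg <- train_config(task = "segmentation", optimizer = "Adam",
                      learning_rate = 3e-3, batch_size = 8L,
                      max_epochs = as.integer(max_epochs),
                      resize_to = 64L, seed = seed)
  init_metrics <- evaluate_model(net, data$val, task = "segmentation",
                                 resize_to = 64L)
  fit <- train_model(net, data, cfg, verbose = verbose)
  val_metrics <- evaluate_model(fit, data$val)
  list(fit = fit, init_dice = init_metrics$dice, final_dice = val_metrics$dice,
       improvement = val_metrics$dice - init_metrics$dice,
       val_metrics = val_metrics)
}

#' Read a configuration file (YAML or JSON)
#'
#' One file can cover model, FEM, augmentation, training and search
#' sections; every protocol constant is a named default of the respective
#' constructor, so the file only needs the fields it overrides.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return nested named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stop_invalid("config must be YAML or JSON: %s", path)
}
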