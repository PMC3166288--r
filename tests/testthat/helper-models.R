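# one small trained model shared across test files (trained once per run)
.model_cache <- new.env(parent = emptyenv())

cached_model <- function() {
  if (is.null(.model_cache$model)) {
    corpus <- generate_training_set(400, 400, seed = 42)
    train <- corpus[corpus$split == "train", ]
    .model_cache$model <- train_model(train$window[train$label == 1L],
                                      train$window[train$label == 0L],
                                      seed = 42)
  }
  .model_cache$model
}
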