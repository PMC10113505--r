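Package: spasatune
Title: Sparrow Search Hyperparameter Optimization for Transfer-Learning
    Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable hyperparameter-optimization toolkit for medical image
    classification. A Sparrow Search Algorithm (SpaSA) optimizer drives a
    continuous [0,1]^D encoding of training hyperparameters (loss, batch size,
    dropout, fine-tune ratio, optimizer, intensity scaler, and augmentation
    settings) for transfer-learning classifiers. Includes image preprocessing
    (bicubic resizing, four intensity scalers), augmentation-based class
    balancing, stratified splitting, a CPU-trainable surrogate convolutional
    backbone with eleven first-order optimizers and six classification losses,
    a one-vs-rest multiclass confusion-metric suite, seeded synthetic image
    fixtures, and a two-stage CT-to-histopathology diagnosis cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
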