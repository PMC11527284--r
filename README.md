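# stresslens

Detecting and profiling psychological stress in short social-media posts
— the kind postgraduate students write about advisors, graduation,
employment, relationships and money. Clinical instruments (scales,
interviews, sensors) are expensive and slow; `stresslens` implements a
text-mining pipeline that works directly on posts:

1. **Cohort filtering** — regular expressions over post text flag
   self-identified postgraduate authors ("I am a master candidate",
   "my advisor", "my research group").
2. **Embedding–topic fusion** — latent Dirichlet allocation fitted by
   collapsed Gibbs sampling is lifted into embedding space: topic *k*'s
   vector is the centroid of token vectors assigned to it,
   `z_i = Σ_k θ̂_ik t_k` combines them per document, each document's
   optimal topic maximizes cosine similarity with its mean embedding,
   and the chosen topic vector is added to every token vector.
3. **Sentiment stratification** — a logistic head over mean-pooled fused
   vectors splits the corpus; the negative side is the *stress document
   set* on which everything downstream operates.
4. **Entity tagging** — a from-scratch peephole **BiLSTM-CRF** labels
   gender (SEX), degree-level (EDU) and institution (ORG) mentions:
   exact CRF training via the forward algorithm, Viterbi decoding,
   hand-derived gradients (finite-difference checked), entity-level
   exact-span P/R/F1.
5. **Stress profiling** — extracted facets cross-tabulate documents into
   mixed-label categories (e.g. "female doctoral"), and each category
   gets a probability distribution over five stress features (research,
   employment, affection, financial, other) estimated from feature-word
   hit counts.

Every stage is backed by a seeded synthetic-corpus generator with planted
ground truth, so the whole pipeline is testable by parameter recovery
without any external data.

## Worked example

Fit topics on a planted three-topic corpus, fuse, and inspect recovery:

```r
library(stresslens)

g   <- generate_topic_corpus(M = 300, K_true = 3, V = 60,
                             tokens_per_doc = 40, seed = 101)
m   <- fit_lda(g$tokens, K = 3, iters = 200, seed = 201)
glance(m)
#> # A tibble: 1 × 7
#>       K alpha  beta iters n_docs n_vocab n_tokens
#>   <int> <dbl> <dbl> <dbl>  <int>   <int>    <int>
#> 1     3  16.7  0.01   200    300      55    12083

tidy(m) |> dplyr::slice_head(n = 3)   # top words per topic
#> # A tibble: 3 × 3
#>   topic token   phi
#>   <int> <chr> <dbl>
#> 1     1 w0019 0.248
#> 2     1 w0020 0.171
#> 3     1 w0006 0.128

sel <- select_topic_count(g$tokens, c(1, 3, 9), seeds_per_K = 3,
                          iters = 200, seed = 17)
sel$table
#> # A tibble: 3 × 3
#>       K mean_perplexity var_perplexity
#>   <int>           <dbl>          <dbl>
#> 1     1            29.0     0
#> 2     3            21.8     0.00000100
#> 3     9            22.2     0.00921
sel$K
#> [1] 3
```

`glance()` reports the fit's shape (`alpha = 50/K` by default); `tidy()`
returns the smoothed topic–word distribution, whose top words recover
each planted topic's vocabulary block. `select_topic_count()` scores
held-out documents by document-completion perplexity (lower is better):
the planted `K = 3` wins against 1 (underfit) and 9 (overfit).

Train and evaluate the entity tagger on planted entities:

```r
tr  <- generate_ner_corpus(n_sentences = 2000, seed = 101)
te  <- generate_ner_corpus(n_sentences = 500,  seed = 102)
mod <- train_ner(tr$sentences,
                 encoder = hash_encoder(dim = 32, seed = 7),
                 hyper = ner_hyper(lr = 0.03, hidden_dim = 50,
                                   dropout = 0.2, batch_size = 128,
                                   epochs = 10, seed = 11))
evaluate_ner(mod, te$sentences)
#> <ner_eval> 500 sentences
#> # A tibble: 4 × 7
#>   entity_type n_gold n_pred n_correct precision recall    f1
#>   <chr>        <int>  <int>     <int>     <dbl>  <dbl> <dbl>
#> 1 SEX            205    205       205         1      1     1
#> 2 EDU            191    191       191         1      1     1
#> 3 ORG            255    255       255         1      1     1
#> 4 overall        651    651       651         1      1     1
```

On this noise-free planted corpus the tagger reaches perfect exact-span
F1; the point is that training, decoding and scoring are correct, not
that real text is this easy (see the methods vignette).

The full pipeline, end to end, with `run_pipeline(posts, config, outdir)`,
writes the stress/positive split, the merged stress-feature map,
extracted entities, the profile table and a manifest with config hash
and artifact checksums. `autoplot()` methods visualize profiles, feature
words and evaluation reports.

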