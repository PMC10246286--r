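* installing to library ‘/root/.R/library’
* installing *source* package ‘striatax’ ...
** using staged installation
** R
** inst
** byte-compile and prepare package for lazy loading
** building package indices
** installing vignettes
** testing if installed package can be loaded from temporary location
** testing if installed package can be loaded from final location
** testing if installed package keeps a record of temporary installation path
* DONE (striatax)
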