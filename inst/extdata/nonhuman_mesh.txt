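Mice
Rats
Drosophila
Drosophila melanogaster
Saccharomyces cerevisiae
Caenorhabditis elegans
Cattle
Zebrafish
Rabbits
Dogs
Swine
Chickens
Xenopus
Arabidopsis
Plants
Escherichia coli
Rats, Sprague-Dawley
Mice, Knockout
Mice, Transgenic
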