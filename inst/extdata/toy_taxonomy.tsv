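taxon	lineage
Arabidopsis thaliana	cellular organisms;Eukaryota;Viridiplantae;Streptophyta;Brassicaceae;Arabidopsis
Oryza sativa	cellular organisms;Eukaryota;Viridiplantae;Streptophyta;Poaceae;Oryza
Phalaenopsis equestris	cellular organisms;Eukaryota;Viridiplantae;Streptophyta;Orchidaceae;Phalaenopsis
Vaccinium corymbosum	cellular organisms;Eukaryota;Viridiplantae;Streptophyta;Ericaceae;Vaccinium
Rhizoctonia solani	cellular organisms;Eukaryota;Opisthokonta;Fungi;Basidiomycota;Rhizoctonia
Tulasnella calospora	cellular organisms;Eukaryota;Opisthokonta;Fungi;Basidiomycota;Tulasnella
Saccharomyces cerevisiae	cellular organisms;Eukaryota;Opisthokonta;Fungi;Ascomycota;Saccharomyces
Pseudomonas fluorescens	cellular organisms;Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonas
Bacillus subtilis	cellular organisms;Bacteria;Firmicutes;Bacilli;Bacillus
Streptomyces coelicolor	cellular organisms;Bacteria;Actinobacteria;Streptomycetales;Streptomyces
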