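geneLink,GO,Symbol,description
https://www.ncbi.nlm.nih.gov/gene/?term=219464,G-protein coupled receptor activity,OR5T2,olfactory receptor family 5 subfamily T member 2
https://www.ncbi.nlm.nih.gov/gene/?term=219464,olfactory receptor activity,OR5T2,olfactory receptor family 5 subfamily T member 2
https://www.ncbi.nlm.nih.gov/gene/?term=219464,plasma membrane,OR5T2,olfactory receptor family 5 subfamily T member 2
https://www.ncbi.nlm.nih.gov/gene/?term=219464,G-protein coupled receptor signaling pathway,OR5T2,olfactory receptor family 5 subfamily T member 2
https://www.ncbi.nlm.nih.gov/gene/?term=219464,integral component of membrane,OR5T2,olfactory receptor family 5 subfamily T member 2
https://www.ncbi.nlm.nih.gov/gene/?term=219464,detection of chemical stimulus involved in sensory perception of smell,OR5T2,olfactory receptor family 5 subfamily T member 2
https://www.ncbi.nlm.nih.gov/gene/?term=390154,G-protein coupled receptor activity,OR5T3,olfactory receptor family 5 subfamily T member 3
https://www.ncbi.nlm.nih.gov/gene/?term=390154,olfactory receptor activity,OR5T3,olfactory receptor family 5 subfamily T member 3
https://www.ncbi.nlm.nih.gov/gene/?term=390154,plasma membrane,OR5T3,olfactory receptor family 5 subfamily T member 3
https://www.ncbi.nlm.nih.gov/gene/?term=390154,G-protein coupled receptor signaling pathway,OR5T3,olfactory receptor family 5 subfamily T member 3
https://www.ncbi.nlm.nih.gov/gene/?term=390154,integral component of membrane,OR5T3,olfactory receptor family 5 subfamily T member 3
https://www.ncbi.nlm.nih.gov/gene/?term=390154,detection of chemical stimulus involved in sensory perception of smell,OR5T3,olfactory receptor family 5 subfamily T member 3
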