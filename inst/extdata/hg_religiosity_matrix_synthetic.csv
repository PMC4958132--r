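taxon,animism,afterlife,shamanism,ancestor_worship,high_gods
Hadza,1,0,0,1,1
Sandawe,1,0,0,1,1
Kung,1,1,1,1,1
Gwi,1,1,1,1,1
Mbuti,1,0,0,1,1
Aka,1,0,0,1,1
Vedda,1,1,1,2,2
Andamanese,1,1,1,2,2
Semang,1,1,1,2,4
Agta,1,1,1,2,1
Badjau,1,1,1,1,1
Aranda,1,1,1,2,2
Tiwi,1,1,1,1,2
Walbiri,1,1,1,2,1
Murngin,1,1,1,2,2
Ainu,1,1,1,4,2
Gilyak,1,1,1,4,1
Yukaghir,1,1,1,4,1
Chukchee,1,1,1,3,1
Aleut,1,1,1,4,2
Copper_Eskimo,1,1,1,3,1
Eyak,1,1,1,1,1
Kaska,1,1,1,1,2
Slave,1,0,1,1,1
Twana,1,1,1,3,1
Yurok,1,1,1,3,1
Montagnais,1,1,1,1,3
Saulteaux,1,1,1,1,3
Gros_Ventre,1,1,1,1,3
Siriono,1,0,0,1,1
Botocudo,1,0,0,1,1
Yahgan,1,1,1,1,4
Aweikoma,1,1,0,1,1
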