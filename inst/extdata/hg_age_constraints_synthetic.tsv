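clade_id	leaf_set	min_age_kya	date_set
root_all	Outgroup;Hadza;Sandawe;Kung;Gwi;Mbuti;Aka;Vedda;Andamanese;Semang;Agta;Badjau;Aranda;Tiwi;Walbiri;Murngin;Ainu;Gilyak;Yukaghir;Chukchee;Aleut;Copper_Eskimo;Eyak;Kaska;Slave;Twana;Yurok;Montagnais;Saulteaux;Gros_Ventre;Siriono;Botocudo;Yahgan;Aweikoma	160	deep
hg_lca	Hadza;Sandawe;Kung;Gwi;Mbuti;Aka;Vedda;Andamanese;Semang;Agta;Badjau;Aranda;Tiwi;Walbiri;Murngin;Ainu;Gilyak;Yukaghir;Chukchee;Aleut;Copper_Eskimo;Eyak;Kaska;Slave;Twana;Yurok;Montagnais;Saulteaux;Gros_Ventre;Siriono;Botocudo;Yahgan;Aweikoma	140	deep
africa	Hadza;Sandawe;Kung;Gwi;Mbuti;Aka	100	deep
non_africa	Vedda;Andamanese;Semang;Agta;Badjau;Aranda;Tiwi;Walbiri;Murngin;Ainu;Gilyak;Yukaghir;Chukchee;Aleut;Copper_Eskimo;Eyak;Kaska;Slave;Twana;Yurok;Montagnais;Saulteaux;Gros_Ventre;Siriono;Botocudo;Yahgan;Aweikoma	85	deep
southern_route	Andamanese;Semang;Agta;Badjau;Aranda;Tiwi;Walbiri;Murngin;Ainu;Gilyak;Yukaghir;Chukchee;Aleut;Copper_Eskimo;Eyak;Kaska;Slave;Twana;Yurok;Montagnais;Saulteaux;Gros_Ventre;Siriono;Botocudo;Yahgan;Aweikoma	70	deep
australia	Aranda;Tiwi;Walbiri;Murngin	50	deep
northeast_asia	Ainu;Gilyak;Yukaghir;Chukchee	30	deep
beringia_america	Aleut;Copper_Eskimo;Eyak;Kaska;Slave;Twana;Yurok;Montagnais;Saulteaux;Gros_Ventre;Siriono;Botocudo;Yahgan;Aweikoma	20	deep
amerind	Twana;Yurok;Montagnais;Saulteaux;Gros_Ventre;Siriono;Botocudo;Yahgan;Aweikoma	16	deep
root_all	Outgroup;Hadza;Sandawe;Kung;Gwi;Mbuti;Aka;Vedda;Andamanese;Semang;Agta;Badjau;Aranda;Tiwi;Walbiri;Murngin;Ainu;Gilyak;Yukaghir;Chukchee;Aleut;Copper_Eskimo;Eyak;Kaska;Slave;Twana;Yurok;Montagnais;Saulteaux;Gros_Ventre;Siriono;Botocudo;Yahgan;Aweikoma	80	shallow
hg_lca	Hadza;Sandawe;Kung;Gwi;Mbuti;Aka;Vedda;Andamanese;Semang;Agta;Badjau;Aranda;Tiwi;Walbiri;Murngin;Ainu;Gilyak;Yukaghir;Chukchee;Aleut;Copper_Eskimo;Eyak;Kaska;Slave;Twana;Yurok;Montagnais;Saulteaux;Gros_Ventre;Siriono;Botocudo;Yahgan;Aweikoma	70	shallow
africa	Hadza;Sandawe;Kung;Gwi;Mbuti;Aka	55	shallow
non_africa	Vedda;Andamanese;Semang;Agta;Badjau;Aranda;Tiwi;Walbiri;Murngin;Ainu;Gilyak;Yukaghir;Chukchee;Aleut;Copper_Eskimo;Eyak;Kaska;Slave;Twana;Yurok;Montagnais;Saulteaux;Gros_Ventre;Siriono;Botocudo;Yahgan;Aweikoma	65	shallow
southern_route	Andamanese;Semang;Agta;Badjau;Aranda;Tiwi;Walbiri;Murngin;Ainu;Gilyak;Yukaghir;Chukchee;Aleut;Copper_Eskimo;Eyak;Kaska;Slave;Twana;Yurok;Montagnais;Saulteaux;Gros_Ventre;Siriono;Botocudo;Yahgan;Aweikoma	60	shallow
australia	Aranda;Tiwi;Walbiri;Murngin	45	shallow
northeast_asia	Ainu;Gilyak;Yukaghir;Chukchee	20	shallow
beringia_america	Aleut;Copper_Eskimo;Eyak;Kaska;Slave;Twana;Yurok;Montagnais;Saulteaux;Gros_Ventre;Siriono;Botocudo;Yahgan;Aweikoma	16	shallow
amerind	Twana;Yurok;Montagnais;Saulteaux;Gros_Ventre;Siriono;Botocudo;Yahgan;Aweikoma	13	shallow
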