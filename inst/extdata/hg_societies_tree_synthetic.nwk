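(Outgroup,(((Hadza,Sandawe),((Kung,Gwi),(Mbuti,Aka))),(Vedda,(Andamanese,(((Aranda,Tiwi),(Walbiri,Murngin)),(((Semang,(Agta,Badjau)),((Ainu,Gilyak),(Yukaghir,Chukchee))),(((Aleut,Copper_Eskimo),(Eyak,(Kaska,Slave))),((Twana,(Yurok,(Montagnais,(Saulteaux,Gros_Ventre)))),((Siriono,Botocudo),(Yahgan,Aweikoma))))))))));
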