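"image_id","order_index","date_label","condition","path"
"portrait_01",1,"1886","low","portrait_01.png"
"portrait_02",2,"1886","low","portrait_02.png"
"portrait_03",3,"1886","low","portrait_03.png"
"portrait_04",4,"1886","low","portrait_04.png"
"portrait_05",5,"1886","low","portrait_05.png"
"portrait_06",6,"1886","low","portrait_06.png"
"portrait_07",7,"1886","low","portrait_07.png"
"portrait_08",8,"1886","low","portrait_08.png"
"portrait_09",9,"1887","high","portrait_09.png"
"portrait_10",10,"1887","high","portrait_10.png"
"portrait_11",11,"1887","high","portrait_11.png"
"portrait_12",12,"1887","high","portrait_12.png"
"portrait_13",13,"1887","low","portrait_13.png"
"portrait_14",14,"1887","low","portrait_14.png"
"portrait_15",15,"1887","low","portrait_15.png"
"portrait_16",16,"1887","low","portrait_16.png"
"portrait_17",17,"1887","low","portrait_17.png"
"portrait_18",18,"1887","low","portrait_18.png"
"portrait_19",19,"1887","low","portrait_19.png"
"portrait_20",20,"1887","low","portrait_20.png"
"portrait_21",21,"1888","high","portrait_21.png"
"portrait_22",22,"1888","high","portrait_22.png"
"portrait_23",23,"1888","high","portrait_23.png"
"portrait_24",24,"1888","low","portrait_24.png"
"portrait_25",25,"1888","low","portrait_25.png"
"portrait_26",26,"1889","low","portrait_26.png"
"portrait_27",27,"1889","high","portrait_27.png"
"portrait_28",28,"1889","high","portrait_28.png"
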