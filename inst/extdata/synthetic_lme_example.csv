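subject,three_level_arbitrated,three_level_advice_only,three_level_card_only,two_level_arbitrated,two_level_advice_only,two_level_card_only,normative_arbitrated,normative_advice_only,normative_card_only
s01,-170.418906589,-228.388108961,-255.224436182,-176.275403164,-233.668139961,-260.144069435,-170.346984494,-227.227990419,-254.178999609
s02,-62.5002522955,-63.657444919,-147.464783751,-67.8606347949,-70.2502979193,-150.958618558,-65.9815059315,-68.364246525,-149.900405625
s03,-45.5025659725,-71.8699189114,-134.667903578,-64.5955778968,-89.7534346455,-152.663741423,-58.8923295902,-83.4506533957,-146.998457792
s04,-80.4455299089,-133.447439729,-145.548491569,-95.7048645418,-147.111115336,-158.055278775,-89.2987370726,-140.114509296,-150.228580086
s05,-126.131883062,-132.241347719,-193.046429327,-136.850928581,-141.413956462,-202.687935356,-126.770413549,-132.31493048,-192.937040075
s06,-75.8622919625,-159.87184011,-114.85194142,-81.6973854036,-164.270731981,-119.383892854,-74.7576622288,-159.49728042,-114.649273408
s07,-177.053961504,-175.704957866,-211.145859424,-212.352818404,-210.989790878,-247.261283224,-197.672148312,-196.306882865,-230.829374118
s08,-116.825010905,-116.899175598,-227.966373196,-153.847480376,-157.096070435,-261.96060677,-140.514983212,-142.163537817,-243.986936937
s09,-56.8545455544,-107.362528585,-118.536499597,-59.6135542076,-109.384386526,-119.93046377,-59.2112759236,-107.807943591,-118.128143557
s10,-35.9415597118,-128.163483812,-81.5715324084,-34.961968609,-127.846597844,-81.3910692801,-36.6220724993,-128.041376182,-81.5159819318
s11,-66.4407636255,-77.8150598994,-157.768166708,-180.286387074,-190.687104349,-260.873935825,-157.082071884,-167.902949823,-236.986340557
s12,-86.8506545902,-120.301518211,-135.150764693,-101.80806816,-136.222156541,-150.680619827,-92.0727733819,-125.723932357,-139.386008275
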